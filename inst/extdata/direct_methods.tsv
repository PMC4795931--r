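method_id	method_name
MI:0018	two hybrid
MI:0397	two hybrid array
MI:0399	two hybrid fragment pooling approach
MI:0055	fluorescent resonance energy transfer
MI:0030	cross-linking study
MI:0872	atomic force microscopy
MI:0114	x-ray crystallography
MI:0077	nuclear magnetic resonance
MI:0065	isothermal titration calorimetry
MI:0107	surface plasmon resonance
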