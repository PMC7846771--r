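res_type,atom,c_mean,c_sd,h_mean,h_sd,weight
ALA,CB,19.0,1.8,1.35,0.22,1.0
ILE,CD1,13.4,1.7,0.75,0.25,1.0
LEU,CD1,24.7,1.6,0.75,0.25,1.0
LEU,CD2,24.0,1.7,0.72,0.25,1.0
VAL,CG1,21.4,1.4,0.82,0.24,1.0
VAL,CG2,21.0,1.5,0.80,0.24,1.0
MET,CE,17.0,1.5,1.95,0.35,1.0
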