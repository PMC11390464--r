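channel,x,y,z
FP1,-0.309,0.951,0
FP2,0.309,0.951,0
F3,-0.35,0.45,0
F4,0.35,0.45,0
C3,-0.5,0,0
C4,0.5,0,0
P3,-0.35,-0.45,0
P4,0.35,-0.45,0
O1,-0.309,-0.951,0
O2,0.309,-0.951,0
F7,-0.809,0.588,0
F8,0.809,0.588,0
T3,-1,0,0
T4,1,0,0
T5,-0.809,-0.588,0
T6,0.809,-0.588,0
FZ,0,0.45,0
CZ,0,0,0
PZ,0,-0.45,0
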