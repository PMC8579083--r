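cad,CR,PR,SD,PD
CR,2,1,0,1
PR,0,3,1,1
SD,0,0,3,1
PD,0,0,0,7
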