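cad,CR,PR,SD,PD
CR,2,1,1,0
PR,0,3,3,2
SD,0,1,0,0
PD,0,0,1,6
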