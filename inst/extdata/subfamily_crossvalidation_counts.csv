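truth,Andreninae,Apinae,Colletinae,Diphaglossinae,Fideliinae,Halictinae,Meganomiinae,Melittinae,Nomadinae,Nomiinae,Nomioidinae,Oxaeinae,Panurginae,Rophitinae,Xylocopinae
Andreninae,20,0,0,0,0,0,0,0,0,0,0,0,0,0,0
Apinae,0,33,0,1,0,0,0,0,0,0,0,0,0,0,0
Colletinae,0,0,20,0,0,0,0,0,0,0,0,0,0,0,0
Diphaglossinae,0,1,0,19,0,0,0,0,0,0,0,0,0,0,0
Fideliinae,0,0,0,0,13,0,0,0,0,0,0,0,0,0,0
Halictinae,0,1,0,0,0,24,0,0,0,0,0,0,0,0,0
Meganomiinae,0,0,0,0,0,0,7,0,0,0,0,0,0,0,0
Melittinae,0,0,0,0,0,0,0,117,0,0,0,0,0,0,0
Nomadinae,0,0,0,0,0,0,0,0,20,0,0,0,0,0,0
Nomiinae,0,0,0,0,0,0,0,0,0,20,0,0,0,0,0
Nomioidinae,0,0,0,0,0,0,0,0,0,0,11,0,0,0,0
Oxaeinae,0,0,0,0,0,0,0,0,0,0,0,5,0,0,0
Panurginae,1,0,0,0,0,0,0,0,0,0,0,0,10,0,0
Rophitinae,0,0,0,0,0,1,0,0,0,0,0,0,0,16,0
Xylocopinae,0,0,0,0,0,0,0,0,0,0,0,0,0,0,20
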