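animal,hemisphere,region,retro_count,coloc_count
Mouse 1,LH,LC,18,4
Mouse 1,RH,LC,32,7
Mouse 2,LH,LC,5,2
Mouse 2,RH,LC,13,6
Mouse 3,LH,LC,20,12
Mouse 3,RH,LC,31,15
Mouse 4,LH,LC,22,12
Mouse 4,RH,LC,14,5
Mouse 1,LH,VTA,0,0
Mouse 1,RH,VTA,0,0
Mouse 2,LH,VTA,0,0
Mouse 2,RH,VTA,0,0
Mouse 3,LH,VTA,0,0
Mouse 3,RH,VTA,0,0
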