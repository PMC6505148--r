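"","PH","FL","FE","NS","SY","NP"
"PH",64.4266,-4.2148,6.373,-0.0049,-103.8781,-114.4456
"FL",-4.2148,5.9607,3.2257,-0.1355,175.777,-21.0909
"FE",6.373,3.2257,23.8617,1.3721,-133.4962,-43.6292
"NS",-0.0049,-0.1355,1.3721,46.2903,370.177,-59.0136
"SY",-103.8781,175.777,-133.4962,370.177,27963.1634,604.6203
"NP",-114.4456,-21.0909,-43.6292,-59.0136,604.6203,872.3525
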