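"","Yield","ASI","PH"
"Yield",0.0956,-0.0027,0.9642
"ASI",-0.0027,0.0654,0.1893
"PH",0.9642,0.1893,23.0647
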