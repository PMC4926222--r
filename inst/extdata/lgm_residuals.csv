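island,res1,res2
Maltese,3.5,0.8
Levanzo,-0.3,-4.3
Lampedusa,4.5,1.6
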