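center,treat,y,n
1,1,30,100
1,2,50,100
2,1,45,100
2,2,75,100
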