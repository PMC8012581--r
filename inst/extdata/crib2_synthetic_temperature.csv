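temp_lo,temp_hi,points
25,30,5
30,32,4
32,34,3
34,35,2
35,35.7,1
35.7,37.5,0
37.5,39,1
39,43,2
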