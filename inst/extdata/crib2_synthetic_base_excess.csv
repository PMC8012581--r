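be_lo,be_hi,points
-30,-22,7
-22,-18,6
-18,-14,5
-14,-11,4
-11,-8,3
-8,-5,2
-5,-2,1
-2,10,0
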