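sex,ga_weeks,bw_lo,bw_hi,points
female,22,0,500,14
female,22,500,750,13
female,22,750,1000,12
female,22,1000,1250,11
female,22,1250,5000,10
female,23,0,500,13
female,23,500,750,12
female,23,750,1000,11
female,23,1000,1250,10
female,23,1250,5000,9
female,24,0,500,12
female,24,500,750,11
female,24,750,1000,10
female,24,1000,1250,9
female,24,1250,5000,8
female,25,0,500,11
female,25,500,750,10
female,25,750,1000,9
female,25,1000,1250,8
female,25,1250,5000,7
female,26,0,500,10
female,26,500,750,9
female,26,750,1000,8
female,26,1000,1250,7
female,26,1250,5000,6
female,27,0,500,9
female,27,500,750,8
female,27,750,1000,7
female,27,1000,1250,6
female,27,1250,5000,5
female,28,0,500,8
female,28,500,750,7
female,28,750,1000,6
female,28,1000,1250,5
female,28,1250,5000,4
female,29,0,500,7
female,29,500,750,6
female,29,750,1000,5
female,29,1000,1250,4
female,29,1250,5000,3
female,30,0,500,6
female,30,500,750,5
female,30,750,1000,4
female,30,1000,1250,3
female,30,1250,5000,2
female,31,0,500,5
female,31,500,750,4
female,31,750,1000,3
female,31,1000,1250,2
female,31,1250,5000,1
female,32,0,500,4
female,32,500,750,3
female,32,750,1000,2
female,32,1000,1250,1
female,32,1250,5000,0
male,22,0,500,15
male,22,500,750,14
male,22,750,1000,13
male,22,1000,1250,12
male,22,1250,5000,11
male,23,0,500,14
male,23,500,750,13
male,23,750,1000,12
male,23,1000,1250,11
male,23,1250,5000,10
male,24,0,500,13
male,24,500,750,12
male,24,750,1000,11
male,24,1000,1250,10
male,24,1250,5000,9
male,25,0,500,12
male,25,500,750,11
male,25,750,1000,10
male,25,1000,1250,9
male,25,1250,5000,8
male,26,0,500,11
male,26,500,750,10
male,26,750,1000,9
male,26,1000,1250,8
male,26,1250,5000,7
male,27,0,500,10
male,27,500,750,9
male,27,750,1000,8
male,27,1000,1250,7
male,27,1250,5000,6
male,28,0,500,9
male,28,500,750,8
male,28,750,1000,7
male,28,1000,1250,6
male,28,1250,5000,5
male,29,0,500,8
male,29,500,750,7
male,29,750,1000,6
male,29,1000,1250,5
male,29,1250,5000,4
male,30,0,500,7
male,30,500,750,6
male,30,750,1000,5
male,30,1000,1250,4
male,30,1250,5000,3
male,31,0,500,6
male,31,500,750,5
male,31,750,1000,4
male,31,1000,1250,3
male,31,1250,5000,2
male,32,0,500,5
male,32,500,750,4
male,32,750,1000,3
male,32,1000,1250,2
male,32,1250,5000,1
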