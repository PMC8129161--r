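3,7,2,6,8,8,3,8,8,6,8,3,4,8,2,6,6,5,4,6,5,9,8,2,2,2,6,5,9,2,6,4,8,8,6,3,9,7,2,2,3,2,1,5,2,7,1,2,9,6
1,9,2,8,3,7,4,6,5,5,6,4,7,3,8,2,9,1,1,9,2,8,3,7,4,6,5,5,6,4,7,3,8,2,9,1,1,9,2,8,3,7,4,6,5,5,6,4,7,3
5,5,5,1,2,3,4,5,6,7,8,9,1,2,3,4,5,6,7,8,9,8,7,6,5,4,3,2,1,5,5,5,1,3,5,7,9,2,4,6,8,1,3,5,7,9,2,4,6,8
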