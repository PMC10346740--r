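K,e1,e2,e3,e4,e5,e6,e7,e8
1.5,-2,-9,-11,-3,-6,-3,-3,-3
1.6,-1,-8,-9,-3,-5,-2,-2,-3
1.7,0,-6,-7,-2,-4,-2,-1,-2
1.8,0,-5,-5,-1,-3,-1,0,-2
1.9,1,-4,-4,0,-2,-1,0,-1
2,2,-2,-2,0,-1,0,1,0
2.1,2,-1,0,1,1,1,2,0
2.2,3,1,2,2,2,1,3,1
2.3,4,2,4,3,3,2,4,1
2.4,5,4,6,4,4,2,4,2
2.5,5,5,8,4,5,3,5,2
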