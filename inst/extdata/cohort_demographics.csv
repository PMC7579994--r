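specimen,age,sex,height_in,weight_lbs,l4_bmd,t_score
1,73,M,71,280,0.722,-3.8
2,75,M,71,350,1.098,-0.4
3,63,F,68,230,0.939,-1.6
4,64,M,67,270,1.001,-2.3
5,80,F,65,160,1.347,2.1
6,70,F,61,250,0.986,-1.2
7,39,F,70,129,0.738,-3.4
8,55,F,67,135,0.879,-2.2
9,24,F,56,110,0.825,-2.6
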