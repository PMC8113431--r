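image_set,reader,category,n,min,max,mean,sd
1.5 min,1,noise,25,1,3,2.5,0.65
1.5 min,1,contrast,25,1,4,2.8,0.69
1.5 min,2,noise,25,1,5,3.0,0.93
1.5 min,2,contrast,25,1,5,3.1,0.93
1.5 min,3,noise,25,2,4,3.0,0.58
1.5 min,3,contrast,25,1,5,3.0,0.79
1.5 min CNN,1,noise,25,4,5,4.5,0.51
1.5 min CNN,1,contrast,25,2,5,4.3,0.80
1.5 min CNN,2,noise,25,3,5,4.4,0.58
1.5 min CNN,2,contrast,25,2,5,4.1,0.76
1.5 min CNN,3,noise,25,3,5,4.4,0.58
1.5 min CNN,3,contrast,25,3,5,3.9,0.81
1 min,1,noise,25,1,2,1.0,0.20
1 min,1,contrast,25,1,3,2.0,0.61
1 min,2,noise,25,1,3,1.7,0.85
1 min,2,contrast,25,1,4,2.3,0.98
1 min,3,noise,25,1,4,2.0,0.87
1 min,3,contrast,25,1,4,2.5,0.82
1 min CNN,1,noise,25,2,4,3.2,0.85
1 min CNN,1,contrast,25,1,5,3.7,0.90
1 min CNN,2,noise,25,3,5,4.1,0.73
1 min CNN,2,contrast,25,2,5,3.7,0.74
1 min CNN,3,noise,25,3,5,4.1,0.70
1 min CNN,3,contrast,25,2,5,3.6,0.71
4 min,1,noise,25,3,5,3.8,0.80
4 min,1,contrast,25,3,5,4.2,0.83
4 min,2,noise,25,3,5,4.2,0.65
4 min,2,contrast,25,3,5,4.3,0.68
4 min,3,noise,25,3,5,4.2,0.55
4 min,3,contrast,25,3,5,4.2,0.78
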