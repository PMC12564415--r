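parameter,group,mean,sd
r,CG,0.0064,0.0026
r,ST,0.0033,0.0016
R0,CG,6.77,4.72
R0,ST,2.74,1.4
lambda,CG,1.0064,0.0027
lambda,ST,1.0033,0.0017
F,CG,40.6,27.53
F,ST,19,8.92
T,CG,357.87,0.69
T,ST,358.66,0.84
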