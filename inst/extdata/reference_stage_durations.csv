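stage,group,mean_days,sd_days,n
egg,CG,13.00,0.00,30
egg,ST3,13.97,0.18,30
egg,ST4,13.33,0.48,30
egg,ST5,13.20,0.41,30
L1,CG,7.00,0.00,30
L1,ST3,7.00,0.00,30
L1,ST4,7.00,0.00,30
L1,ST5,7.00,0.00,30
L2,CG,6.00,0.00,30
L2,ST3,6.00,0.00,30
L2,ST4,5.83,0.38,30
L2,ST5,6.00,0.00,30
L3,CG,5.69,0.10,30
L3,ST3,11.60,0.40,30
L3,ST4,5.47,0.51,30
L3,ST5,5.73,0.57,30
L4,CG,4.34,0.09,30
L4,ST3,4.77,0.43,30
L4,ST4,7.03,0.18,30
L4,ST5,4.33,0.48,30
L5,CG,8.48,0.09,30
L5,ST3,7.20,0.41,30
L5,ST4,8.37,0.49,30
L5,ST5,11.23,0.41,30
pupa,CG,313.20,0.97,14
pupa,ST3,308.14,0.71,6
pupa,ST4,309.00,0.00,2
pupa,ST5,308.75,0.85,5
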