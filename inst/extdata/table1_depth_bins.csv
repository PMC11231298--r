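variable,group,bin_lo_um,mean,sd
a_bar,FED,0,3.34,1.78
a_bar,FED,100,4.02,0.56
a_bar,FED,200,4.48,0.63
a_bar,FED,300,3.93,0.54
a_bar,FED,400,3.54,1.51
a_bar,FED,500,2.41,0.37
a_bar,FED,600,2.2,0.29
a_bar,FED,700,0.95,0.83
a_bar,FED,800,0.31,0.62
a_bar,BD,0,2.54,0.46
a_bar,BD,100,2.43,0.28
a_bar,BD,200,2.56,0.19
a_bar,BD,300,2.85,0.76
a_bar,BD,400,2.38,0.28
a_bar,BD,500,2.11,0.35
a_bar,BD,600,1.83,0.69
a_bar,BD,700,1.57,0.54
a_bar,BD,800,1.05,0.27
a_bar,control,0,6.02,1.37
a_bar,control,100,6.47,0.97
a_bar,control,200,4.76,0.53
a_bar,control,300,2.61,0.49
a_bar,control,400,2.14,0.61
a_bar,control,500,2.01,0.46
a_bar,control,600,1.76,0.69
a_bar,control,700,2.24,0.51
a_bar,control,800,3.86,1.46
alpha1,FED,0,40,5
alpha1,FED,100,48,6
alpha1,FED,200,42,8
alpha1,FED,300,40,8
alpha1,FED,400,48,8
alpha1,FED,500,29,5
alpha1,FED,600,25,4
alpha1,FED,700,32,14
alpha1,FED,800,29,0
alpha1,BD,0,40,4
alpha1,BD,100,28,2
alpha1,BD,200,33,3
alpha1,BD,300,43,3
alpha1,BD,400,34,6
alpha1,BD,500,38,10
alpha1,BD,600,55,11
alpha1,BD,700,33,11
alpha1,BD,800,25,11
alpha1,control,0,11,11
alpha1,control,100,15,4
alpha1,control,200,23,5
alpha1,control,300,26,4
alpha1,control,400,28,7
alpha1,control,500,28,12
alpha1,control,600,31,6
alpha1,control,700,30,2
alpha1,control,800,30,5
alpha2,FED,0,-35,7
alpha2,FED,100,-20,4
alpha2,FED,200,-14,4
alpha2,FED,300,-36,5
alpha2,FED,400,-26,8
alpha2,FED,500,-59,15
alpha2,FED,600,-38,7
alpha2,FED,700,-19,17
alpha2,FED,800,-57,0
alpha2,BD,0,-35,7
alpha2,BD,100,-45,3
alpha2,BD,200,-36,2
alpha2,BD,300,-30,5
alpha2,BD,400,-32,5
alpha2,BD,500,-26,4
alpha2,BD,600,-32,8
alpha2,BD,700,-23,3
alpha2,BD,800,-20,10
alpha2,control,0,-11,11
alpha2,control,100,-7,7
alpha2,control,200,-3,3
alpha2,control,300,1,6
alpha2,control,400,-2,4
alpha2,control,500,-6,11
alpha2,control,600,1,7
alpha2,control,700,7,4
alpha2,control,800,5,7
delta_alpha,FED,0,39,5
delta_alpha,FED,100,44,4
delta_alpha,FED,200,36,4
delta_alpha,FED,300,35,4
delta_alpha,FED,400,35,5
delta_alpha,FED,500,51,5
delta_alpha,FED,600,36,6
delta_alpha,FED,700,49,7
delta_alpha,FED,800,42,0
delta_alpha,BD,0,52,4
delta_alpha,BD,100,52,3
delta_alpha,BD,200,47,4
delta_alpha,BD,300,43,3
delta_alpha,BD,400,38,3
delta_alpha,BD,500,38,4
delta_alpha,BD,600,39,3
delta_alpha,BD,700,39,5
delta_alpha,BD,800,43,7
delta_alpha,control,0,22,9
delta_alpha,control,100,22,6
delta_alpha,control,200,26,6
delta_alpha,control,300,25,7
delta_alpha,control,400,30,4
delta_alpha,control,500,33,4
delta_alpha,control,600,30,5
delta_alpha,control,700,23,4
delta_alpha,control,800,25,8
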