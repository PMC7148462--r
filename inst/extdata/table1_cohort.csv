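variable,mean,sd,min,max
age,86.5,6.0,75,101
height,154.1,7.8,138.0,165.0
weight,45.5,10.0,32.0,68.7
bmi,19.1,3.5,13.9,27.3
scr,0.91,0.31,0.60,1.55
clcr,38.0,11.1,21.5,59.1
albumin,2.9,0.6,2.1,3.7
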