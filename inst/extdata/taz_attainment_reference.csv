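taz_dose_g,tau,clcr,attain
0.5,6,60,TRUE
0.5,6,50,TRUE
0.5,6,40,TRUE
0.5,6,30,TRUE
0.5,6,20,TRUE
0.5,6,10,TRUE
0.5,8,60,TRUE
0.5,8,50,TRUE
0.5,8,40,TRUE
0.5,8,30,TRUE
0.5,8,20,TRUE
0.5,8,10,TRUE
0.5,12,60,FALSE
0.5,12,50,FALSE
0.5,12,40,TRUE
0.5,12,30,TRUE
0.5,12,20,TRUE
0.5,12,10,TRUE
0.25,6,60,FALSE
0.25,6,50,FALSE
0.25,6,40,TRUE
0.25,6,30,TRUE
0.25,6,20,TRUE
0.25,6,10,TRUE
0.25,8,60,FALSE
0.25,8,50,FALSE
0.25,8,40,FALSE
0.25,8,30,FALSE
0.25,8,20,TRUE
0.25,8,10,TRUE
0.25,12,60,FALSE
0.25,12,50,FALSE
0.25,12,40,FALSE
0.25,12,30,FALSE
0.25,12,20,FALSE
0.25,12,10,FALSE
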