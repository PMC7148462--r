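parameter,estimate,se,ci_lower,ci_upper
theta1,4.58,0.289,4.04,5.22
theta2,0.061,0.0293,0.0107,0.114
theta3,5.39,0.969,3.81,8.33
theta4,20.7,6.11,12.0,37.1
theta5,6.96,0.314,5.09,7.84
omega2_CL,0.0705,0.0177,0.0357,0.104
omega2_Vc,0.389,0.153,0.118,0.803
omega2_Q,0.311,0.327,0.00990,1.40
omega2_Vp,0,NA,NA,NA
sigma2_prop,0.000927,0.000798,0.000170,0.00289
sigma2_add,25.1,12.8,3.72,46.6
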