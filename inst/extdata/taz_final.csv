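parameter,estimate,se,ci_lower,ci_upper
theta1,5.00,0.318,4.41,5.78
theta2,0.0587,0.0298,0.0116,0.125
theta3,6.29,1.04,4.13,11.1
theta4,24.0,8.44,9.90,44.6
theta5,7.73,0.443,5.61,8.31
omega2_CL,0.0715,0.0221,0.0301,0.125
omega2_Vc,0.547,0.244,0.169,1.11
omega2_Q,0.545,0.465,0.0340,1.79
omega2_Vp,0,NA,NA,NA
sigma2_prop,0.000479,0.000749,0.0000499,0.00252
sigma2_add,0.394,0.223,0.0297,0.602
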