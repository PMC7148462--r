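mic,clcr,regimen,caution
2,60,4.5 g q8h,FALSE
2,50,4.5 g q8h,FALSE
2,40,2.25 g q6h,FALSE
2,30,2.25 g q6h,TRUE
2,20,2.25 g q8h,TRUE
2,10,2.25 g q8h,TRUE
4,60,4.5 g q8h,FALSE
4,50,4.5 g q8h,FALSE
4,40,2.25 g q6h,FALSE
4,30,2.25 g q6h,TRUE
4,20,2.25 g q8h,TRUE
4,10,2.25 g q8h,TRUE
8,60,4.5 g q6h,FALSE
8,50,4.5 g q6h,FALSE
8,40,2.25 g q6h,FALSE
8,30,2.25 g q6h,TRUE
8,20,2.25 g q8h,TRUE
8,10,2.25 g q8h,TRUE
16,60,-,FALSE
16,50,4.5 g q6h,FALSE
16,40,4.5 g q6h,FALSE
16,30,2.25 g q6h,TRUE
16,20,2.25 g q6h,TRUE
16,10,2.25 g q8h,TRUE
32,60,-,FALSE
32,50,-,FALSE
32,40,-,FALSE
32,30,4.5 g q6h,TRUE
32,20,4.5 g q6h,TRUE
32,10,2.25 g q6h,TRUE
64,60,-,FALSE
64,50,-,FALSE
64,40,-,FALSE
64,30,-,FALSE
64,20,-,FALSE
64,10,4.5 g q6h,TRUE
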