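regimen,clcr,breakpoint
4.5 g q6h,60,8
4.5 g q6h,50,16
4.5 g q6h,40,16
4.5 g q6h,30,32
4.5 g q6h,20,32
4.5 g q6h,10,64
4.5 g q8h,60,2
4.5 g q8h,50,4
4.5 g q8h,40,8
4.5 g q8h,30,8
4.5 g q8h,20,16
4.5 g q8h,10,32
4.5 g q12h,60,0.125
4.5 g q12h,50,0.25
4.5 g q12h,40,0.5
4.5 g q12h,30,1
4.5 g q12h,20,2
4.5 g q12h,10,4
2.25 g q6h,60,8
2.25 g q6h,50,8
2.25 g q6h,40,16
2.25 g q6h,30,16
2.25 g q6h,20,16
2.25 g q6h,10,32
2.25 g q8h,60,1
2.25 g q8h,50,2
2.25 g q8h,40,8
2.25 g q8h,30,8
2.25 g q8h,20,8
2.25 g q8h,10,16
2.25 g q12h,60,0.063
2.25 g q12h,50,0.125
2.25 g q12h,40,0.25
2.25 g q12h,30,0.5
2.25 g q12h,20,1
2.25 g q12h,10,2
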