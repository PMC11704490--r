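age_lo,age_hi,sex,index,mean,sd,source
20,30,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
20,30,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
20,30,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
20,30,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
20,30,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
20,30,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
20,30,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
20,30,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
20,30,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
20,30,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
30,40,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
30,40,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
30,40,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
30,40,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
30,40,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
30,40,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
30,40,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
30,40,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
30,40,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
30,40,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
40,50,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
40,50,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
40,50,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
40,50,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
40,50,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
40,50,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
40,50,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
40,50,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
40,50,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
40,50,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
50,60,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
50,60,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
50,60,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
50,60,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
50,60,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
50,60,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
50,60,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
50,60,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
50,60,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
50,60,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
60,70,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
60,70,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
60,70,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
60,70,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
60,70,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
60,70,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
60,70,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
60,70,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
60,70,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
60,70,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
70,80,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
70,80,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
70,80,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
70,80,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
70,80,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
70,80,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
70,80,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
70,80,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
70,80,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
70,80,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
80,90,F,rmssd,47,14,synthetic stand-in derived from published normal ranges
80,90,F,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
80,90,F,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
80,90,F,lf_power,1170,416,synthetic stand-in derived from published normal ranges
80,90,F,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
80,90,M,rmssd,47,14,synthetic stand-in derived from published normal ranges
80,90,M,hrt_ts,7.5,2.5,synthetic stand-in derived from published normal ranges
80,90,M,brs,19.47,7.3,synthetic stand-in derived from published normal ranges
80,90,M,lf_power,1170,416,synthetic stand-in derived from published normal ranges
80,90,M,lf_hf,2.8,1.3,synthetic stand-in derived from published normal ranges
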