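# Reference mean HK parameter estimates (epsilon, sigma, c), BIC-based
# likelihood values (L_hk, L_okrr with the selected single model) and
# organization-section labels per (alpha, rho) grid cell, with the printed
# intensity-SNR value (snr_ref) each cell should reproduce to 2 decimals.
alpha,rho,epsilon,sigma,c,L_hk,okrr,L_okrr,section,snr_ref
0.1,1,0.01,0.17,1.00,511,K,513,*,0.58
0.1,5,0.10,0.21,1.25,245,K,239,*,0.65
0.1,10,0.14,0.20,2.55,259,K,259,*,0.78
0.1,50,0.01,0.25,6.82,159,RA,157,**,0.88
0.1,100,0.24,0.26,100.00,96,RA,95,**,0.99
1,1,0.01,0.26,1.92,220,K,220,*,0.70
1,5,0.36,0.16,5.61,240,RA,241,**,0.97
1,10,0.53,0.14,6.70,268,RI,267,***,1.12
1,50,0.33,0.15,6.82,504,RI,501,****,0.96
1,100,0.27,0.23,3.08,138,RA,136,****,0.85
10,1,0.01,0.29,12.84,179,RA,179,**,0.93
10,5,0.54,0.16,5.69,232,RI,228,***,1.09
10,10,0.60,0.11,40.26,409,RI,409,***,1.02
10,50,0.01,0.26,2.51,149,K,149,****,0.75
10,100,0.10,0.24,1.27,169,K,168,****,0.65
100,1,0.01,0.30,100.00,168,RA,168,**,0.99
100,5,0.52,0.13,6.38,298,RI,297,***,1.15
100,10,0.69,0.11,14.02,411,RI,410,***,1.21
100,50,0.11,0.16,1.10,449,K,421,****,0.67
100,100,0.09,0.20,1.10,198,K,195,****,0.63
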