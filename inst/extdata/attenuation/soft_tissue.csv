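energy_kev,mu_rho,muen_rho
5,41.87,40.85
6,24.18,23.56
8,10.45,10.21
10,5.367,4.990
15,1.693,1.396
20,0.8205,0.5663
30,0.3784,0.1610
40,0.2688,0.07184
50,0.2264,0.04305
60,0.2048,0.03205
80,0.1823,0.02541
100,0.1693,0.02455
150,0.1492,0.02650
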