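energy_kev,mu_rho,muen_rho
5,25.40,24.90
6,14.70,14.30
8,6.400,6.200
10,3.270,2.935
15,1.083,0.8152
20,0.5677,0.3344
30,0.3063,0.09687
40,0.2396,0.04671
50,0.2123,0.03161
60,0.1974,0.02629
80,0.1800,0.02409
100,0.1688,0.02453
150,0.1500,0.02758
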