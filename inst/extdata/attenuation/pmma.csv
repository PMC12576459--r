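energy_kev,mu_rho,muen_rho
5,26.20,25.90
6,15.10,14.90
8,6.530,6.400
10,3.357,3.026
15,1.101,0.8656
20,0.5714,0.3460
30,0.3032,0.09645
40,0.2350,0.04599
50,0.2074,0.03067
60,0.1924,0.02530
80,0.1751,0.02302
100,0.1641,0.02342
150,0.1456,0.02631
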