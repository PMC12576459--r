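energy_kev,mu_rho,muen_rho
5,16.30,15.80
6,9.350,9.000
8,3.920,3.740
10,2.047,1.823
15,0.7551,0.4927
20,0.4290,0.2003
30,0.2621,0.06343
40,0.2177,0.03374
50,0.1982,0.02530
60,0.1868,0.02278
80,0.1724,0.02271
100,0.1624,0.02417
150,0.1448,0.02770
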