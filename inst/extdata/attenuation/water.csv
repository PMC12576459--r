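energy_kev,mu_rho,muen_rho
5,41.58,40.44
6,24.05,23.46
8,10.37,10.16
10,5.329,4.944
15,1.673,1.374
20,0.8096,0.5503
30,0.3756,0.1557
40,0.2683,0.06947
50,0.2269,0.04223
60,0.2059,0.03190
80,0.1837,0.02583
100,0.1707,0.02539
150,0.1505,0.02762
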