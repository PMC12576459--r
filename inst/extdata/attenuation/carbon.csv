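energy_kev,mu_rho,muen_rho
5,19.10,18.40
6,10.90,10.50
8,4.576,4.360
10,2.373,2.078
15,0.8071,0.5627
20,0.4420,0.2238
30,0.2562,0.06614
40,0.2076,0.03343
50,0.1871,0.02397
60,0.1753,0.02098
80,0.1610,0.02037
100,0.1514,0.02147
150,0.1347,0.02449
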