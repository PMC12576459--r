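fan_angle_deg,al_mm
0,0
2,0.10
4,0.35
6,0.80
8,1.50
10,2.50
12,3.90
14,5.70
16,8.00
18,11.00
20,14.50
22,18.50
23.5,22.00
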