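id,name,density,z_a,zeff,table,components
1,air,0.001205,0.49919,7.64,air,
2,lung,0.260,0.54990,7.52,soft_tissue,
3,adipose,0.950,0.55579,6.44,adipose,
4,soft_tissue,1.040,0.54990,7.52,soft_tissue,
5,water,1.000,0.55509,7.42,water,
6,pmma,1.190,0.53937,6.53,pmma,
7,bone_mix,1.300,0.53235,10.60,,soft_tissue:0.5;bone_cortical:0.5
8,bone_cortical,1.920,0.51480,13.92,bone_cortical,
9,aluminum,2.700,0.48181,13.00,aluminum,
10,carbon_fiber,1.600,0.49954,6.00,carbon,
11,styrofoam,0.015,0.53768,5.74,polystyrene,
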