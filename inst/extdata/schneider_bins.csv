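hu_lo,hu_hi,material,dens_a,dens_b
-1100,-950,air,0.002205,0.000001
-950,-120,lung,1.030,0.001
-120,-22,adipose,1.030,0.001
-22,120,soft_tissue,1.030,0.001
120,600,bone_mix,1.08724,0.000523
600,3100,bone_cortical,1.08724,0.000523
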