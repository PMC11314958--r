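roi_name,atlas_label
superior_frontal_gyrus,R_SFG
anterior_cingulate_gyrus,R_ACG
posterior_cingulate_gyrus,R_PCG
dorsal_anterior_insula,R_dAI
middle_temporal_gyrus,R_MTG
entorhinal_cortex,R_ENT
parahippocampal_gyrus,R_PHG
fusiform_gyrus,R_FuG
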