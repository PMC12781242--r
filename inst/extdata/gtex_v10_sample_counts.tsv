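tissue	n_male	n_female
adipose_subcutaneous	481	233
adipose_visceral_omentum	407	180
adrenal_gland	184	111
artery_aorta	308	164
artery_coronary	168	100
artery_tibial	471	220
bladder	48	29
brain_amygdala	129	52
brain_anterior_cingulate_cortex	177	56
brain_caudate_basal_ganglia	224	76
brain_cerebellar_hemisphere	202	75
brain_cerebellum	194	72
brain_cortex	195	75
brain_frontal_cortex_ba9	201	68
brain_hippocampus	190	65
brain_hypothalamus	193	64
brain_nucleus_accumbens_basal_ganglia	212	73
brain_putamen_basal_ganglia	193	61
brain_spinal_cord_cervical_c-1	136	68
brain_substantia_nigra	133	50
breast_mammary_tissue	336	178
colon_sigmoid	268	151
colon_transverse	307	172
esophagus_gastroesophageal_junction	266	137
esophagus_mucosa	399	215
esophagus_muscularis	368	193
heart_atrial_appendage	318	143
heart_left_ventricle	308	144
kidney_cortex	80	24
liver	184	78
lung	414	190
minor_salivary_gland	129	52
muscle_skeletal	552	266
nerve_tibial	459	211
pancreas	223	139
pituitary	229	84
skin_not_sun_exposed_suprapubic	445	206
skin_sun_exposed_lower_leg	506	248
small_intestine_terminal_ileum	135	72
spleen	176	101
stomach	259	148
thyroid	459	225
whole_blood	541	262
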