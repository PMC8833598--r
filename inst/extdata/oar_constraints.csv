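structure,metric,arg,threshold,comparator
brain_stem,Dmax,,54,<
cochlea,Dmax,,45,<
chiasm,Dmax,,55,<
optic_nerve,Dmax,,55,<
spinal_cord,Dmax,,50,<
pituitary_gland,Dmax,,45,<
brain,Dmean,,30,<
parotid_gland,Dmean,,26,<
lens,Dmax,,5,<
heart,Dmax,,26,<
trachea,Dmax,,32,<
aorta,Dmax,,45,<
esophagus,Dmean,,34,<
lung,VGy,20,20,<
lung,Dmean,,7,<
myelon,Dmax,,45,<
small_bowel,Dcc,150,30,<
kidney,Vpct,50,14,<
liver,Dmean,,30,<
breast_contralateral,Dmax,,2.64,<
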