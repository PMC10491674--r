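organ,target_organ_system
liver,liver
gallbladder,liver
thymus,lymphoid_tissues
thymus gland,lymphoid_tissues
spleen,lymphoid_tissues
lymph node,lymphoid_tissues
mandibular lymph node,lymphoid_tissues
mesenteric lymph node,lymphoid_tissues
bone marrow,lymphoid_tissues
thyroid gland,endocrine_system
parathyroid gland,endocrine_system
adrenal gland,endocrine_system
pituitary gland,endocrine_system
pancreas islets,endocrine_system
stomach,gi_tract
duodenum,gi_tract
jejunum,gi_tract
ileum,gi_tract
cecum,gi_tract
colon,gi_tract
rectum,gi_tract
esophagus,gi_tract
salivary gland,gi_tract
kidney,urinary_system
urinary bladder,urinary_system
ureter,urinary_system
testis,reproductive_system
epididymis,reproductive_system
prostate,reproductive_system
seminal vesicle,reproductive_system
ovary,reproductive_system
uterus,reproductive_system
vagina,reproductive_system
mammary gland,reproductive_system
brain,nervous_system
spinal cord,nervous_system
sciatic nerve,nervous_system
optic nerve,nervous_system
eye,eye_conjunctiva
conjunctiva,eye_conjunctiva
cornea,eye_conjunctiva
lacrimal gland,eye_conjunctiva
skin,cutaneous
injection site,cutaneous
subcutis,cutaneous
skeletal muscle,muscular_skeletal_system
bone,muscular_skeletal_system
femur,muscular_skeletal_system
sternum,muscular_skeletal_system
joint,muscular_skeletal_system
heart,cardiovascular_system
aorta,cardiovascular_system
lung,respiratory_system
trachea,respiratory_system
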