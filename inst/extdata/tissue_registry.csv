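name,class,k_per_spring,n_springs,attachment_area,origin_set,insertion_set,co_modeled_with
anterior_sacroiliac,ligament,230,10,,anterior_sacroiliac_origin,anterior_sacroiliac_insertion,
long_posterior_sacroiliac,ligament,150,6,,long_posterior_sacroiliac_origin,long_posterior_sacroiliac_insertion,
short_posterior_sacroiliac,ligament,150,4,,short_posterior_sacroiliac_origin,short_posterior_sacroiliac_insertion,
sacrospinous,ligament,200,3,,sacrospinous_origin,sacrospinous_insertion,
sacrotuberous,ligament,80,6,,sacrotuberous_origin,sacrotuberous_insertion,
iliolumbar,ligament,200,5,,iliolumbar_origin,iliolumbar_insertion,
inguinal,ligament,250,1,,inguinal_origin,inguinal_insertion,
supraspinous,ligament,15,1,,supraspinous_origin,supraspinous_insertion,
intertransverse,ligament,15,1,,intertransverse_origin,intertransverse_insertion,
gluteus_maximus,muscle,962,5,4822,gluteus_maximus_origin,gluteus_maximus_insertion,
gluteus_medius,muscle,,,,gluteus_medius_origin,gluteus_medius_insertion,gluteus_maximus
gluteus_minimus,muscle,,,,gluteus_minimus_origin,gluteus_minimus_insertion,gluteus_maximus
pectineus,muscle,158,2,196,pectineus_origin,pectineus_insertion,
adductor_magnus,muscle,250,1,330,adductor_magnus_origin,adductor_magnus_insertion,
adductor_longus,muscle,67,2,95,adductor_longus_origin,adductor_longus_insertion,
piriformis,muscle,168,1,60,piriformis_origin,piriformis_insertion,
gemellus_superior,muscle,198,3,667,gemellus_superior_origin,gemellus_superior_insertion,
gemellus_inferior,muscle,,,,gemellus_inferior_origin,gemellus_inferior_insertion,gemellus_superior
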