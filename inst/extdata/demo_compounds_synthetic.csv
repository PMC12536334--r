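compound_id,name,chem_class,pnec_ng_L,ec50_ug_L,bcf_L_kg,pc_crit_mg_L,rs_hlb_L_day,rs_anion_L_day,rs_cation_L_day,lod_water,loq_water,lod_psd,loq_psd,lod_biota,loq_biota
imidacloprid,Imidacloprid,pesticide,6.8,1.992235,100;85,NA,NA,0.045,0.039,1,3,0.002,0.006,0.5,1.5
citalopram,Citalopram,pharmaceutical,1600,NA,1200;800,1.4e-4,0.03,0.028,0.051,1,3,0.002,0.006,0.5,1.5
clopidogrel,Clopidogrel,pharmaceutical,NA,NA,15600,6.4e-6,0.02,0.022,0.035,1,3,0.002,0.006,0.5,1.5
sulfapyridine,Sulfapyridine,pharmaceutical,NA,NA,300,NA,0.026,0.024,0.029,1,3,0.002,0.006,0.5,1.5
atrazine,Atrazine,pesticide,600,85,45;30,NA,0.041,0.038,NA,1,3,0.002,0.006,0.5,1.5
nicotine,Nicotine,other,2400,NA,,NA,0.035,NA,0.062,1,3,0.002,0.006,0.5,1.5
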