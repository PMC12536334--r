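compound_id,sorbent,time_days,mass_ng,c_lab_ng_L
imidacloprid,anion,1,22.5,500
imidacloprid,anion,2,45,500
imidacloprid,anion,3,67.5,500
imidacloprid,anion,5,112.5,500
imidacloprid,anion,7,157.5,500
imidacloprid,cation,1,19.5,500
imidacloprid,cation,2,39,500
imidacloprid,cation,3,58.5,500
imidacloprid,cation,5,97.5,500
imidacloprid,cation,7,136.5,500
citalopram,hlb,1,15,500
citalopram,hlb,2,30,500
citalopram,hlb,3,45,500
citalopram,hlb,5,75,500
citalopram,hlb,7,105,500
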