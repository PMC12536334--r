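compound_id,matrix,timepoint,replicate,value,censor
imidacloprid,water,2021-07,1,52,quantified
imidacloprid,water,2021-08,1,60,quantified
imidacloprid,water,2021-09,1,89,quantified
imidacloprid,water,2021-10,1,75,quantified
imidacloprid,water,2021-11,1,62,quantified
imidacloprid,water,2021-12,1,58,quantified
imidacloprid,biota,2021-07,1,50,quantified
imidacloprid,biota,2021-08,1,55,quantified
imidacloprid,biota,2021-09,1,78,quantified
imidacloprid,biota,2021-10,1,70,quantified
imidacloprid,biota,2021-11,1,60,quantified
imidacloprid,biota,2021-12,1,65,quantified
citalopram,biota,2021-07,1,127.1,quantified
citalopram,biota,2021-08,1,112,quantified
citalopram,biota,2021-09,1,104,quantified
citalopram,biota,2021-10,1,95,quantified
citalopram,biota,2021-11,1,88,quantified
citalopram,biota,2021-12,1,79.9,quantified
clopidogrel,biota,2021-07,1,0.075,quantified
clopidogrel,biota,2021-08,1,0.078,quantified
clopidogrel,biota,2021-09,1,0.082,quantified
clopidogrel,biota,2021-10,1,0.085,quantified
clopidogrel,biota,2021-11,1,0.08,quantified
clopidogrel,biota,2021-12,1,0.08,quantified
imidacloprid,psd_hlb,2021-07,1,2.570623100602213,quantified
imidacloprid,psd_hlb,2021-08,1,3.23622274549324,quantified
imidacloprid,psd_hlb,2021-09,1,4.0741630525277275,quantified
imidacloprid,psd_hlb,2021-10,1,5.129067398620052,quantified
imidacloprid,psd_hlb,2021-11,1,6.457113286927785,quantified
imidacloprid,psd_hlb,2021-12,1,8.129024003747151,quantified
imidacloprid,psd_anion,2021-07,1,3.427980998667188,quantified
imidacloprid,psd_anion,2021-08,1,3.846257941501059,quantified
imidacloprid,psd_anion,2021-09,1,4.31557239036967,quantified
imidacloprid,psd_anion,2021-10,1,4.842151862870807,quantified
imidacloprid,psd_anion,2021-11,1,5.432983748673675,quantified
imidacloprid,psd_anion,2021-12,1,6.095908027934525,quantified
imidacloprid,psd_cation,2021-07,1,2.041918509642815,quantified
imidacloprid,psd_cation,2021-08,1,2.5706231006022136,quantified
imidacloprid,psd_cation,2021-09,1,3.23622274549324,quantified
imidacloprid,psd_cation,2021-10,1,4.074163052527728,quantified
imidacloprid,psd_cation,2021-11,1,5.129067398620052,quantified
imidacloprid,psd_cation,2021-12,1,6.457113286927785,quantified
atrazine,water,2021-10,1,10,quantified
atrazine,water,2021-07,1,,not_detected
sulfapyridine,biota,2021-07,1,12,quantified
nicotine,water,2021-10,1,1350,quantified
citalopram,psd_hlb,2021-07,1,,detected_below_loq
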