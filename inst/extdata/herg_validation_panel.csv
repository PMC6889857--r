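drug,channel,ic50_uM,ic50_censored,hill,cmax_free_uM,risk,dataset,dyn_ic50_uM,dyn_max_inhib,dyn_hill,external_metric,cell_model,source,temperature_C,technique
Ibutilide,IKr,2,false,1,,,validation,,,,,XO,B17,21.5,Voltage-clamp 2-electrode
Azimilide,IKr,0.61,false,1,,,validation,,,,,CHO,B32,22,Whole-cell PC
Disopyramide,IKr,7.23,false,0.89,,,validation,,,,,CHO,B26,36,Whole-cell PC
Domperidone,IKr,0.057,false,0.99,,,validation,,,,,HEK,B3,21,Whole-cell PC
Droperidol,IKr,0.0322,false,1.39,,,validation,,,,,HEK,B7,22.5,Whole-cell PC
Pimozide,IKr,0.001,false,1.1,,,validation,,,,,HEK,B10,35,Whole-cell PC
Astemizole,IKr,0.0013,false,0.95,,,validation,,,,,HEK,B31,35,Whole-cell PC
Clozapine,IKr,2.5,false,0.82,,,validation,,,,,HEK,B12,35,Whole-cell PC
Clarithromycin,IKr,750,false,1.7,,,validation,,,,,CHO,B1,,Whole-cell PC
Risperidone,IKr,0.167,false,1,,,validation,,,,,CHO,B11,23,Whole-cell PC
Metoprolol,IKr,145,false,1.1,,,validation,,,,,HEK,B9,23,Whole-cell PC
Tamoxifen,IKr,1.2,false,1.4,,,validation,,,,,HEK,B2,23,Whole-cell PC
Nifedipine,IKr,50,true,,,,validation,,,,,HEK,B33,23,Whole-cell PC
Nitrendipine,IKr,10,false,,,,validation,,,,,,B28,,
Loratadine,IKr,173,false,,,,validation,,,,,HEK,B6,36 +/- 1,Whole-cell PC
Vandetanib,IKr,1.15,false,0.76,,,validation,,,,,HEK,B13,37 +/- 0.5,Whole-cell PC
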