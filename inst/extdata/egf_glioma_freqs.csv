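study,year,ethnicity,source,n_case,n_control,case_fGG,case_fGA,case_fAA,ctrl_fGG,ctrl_fGA,ctrl_fAA
Bao 2011,2011,Asian,Hospital,160,320,0.400,0.444,0.156,0.441,0.472,0.088
Wang 2010,2010,Asian,Population,672,693,0.443,0.454,0.103,0.528,0.398,0.074
Pinto 2009,2009,Caucasian,Hospital,165,200,0.285,0.479,0.236,0.280,0.460,0.260
Liu 2009,2009,Asian,Hospital,168,194,0.446,0.464,0.089,0.474,0.443,0.082
Costa 2007,2007,Caucasian,Hospital,197,570,0.284,0.492,0.223,0.230,0.467,0.304
Vauleon 2007,2007,Caucasian,Population,209,214,0.211,0.488,0.301,0.145,0.561,0.294
Bhowmick 2004,2004,Caucasian,Hospital,42,76,0.357,0.381,0.262,0.158,0.487,0.355
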