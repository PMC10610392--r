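genotype,prior,posterior,cv_posterior
G01,T,T,HS
G02,HT,HT,T
G03,HT,HT,HT
G04,T,HT,HT
G05,HT,HT,HT
G06,S,S,S
G07,HT,T,T
G08,S,S,S
G09,HT,HT,HS
G10,T,T,S
G11,HS,HS,HS
G12,HS,S,S
G13,HS,HS,HS
G14,T,T,S
G15,M,M,S
G16,T,T,HS
G17,HS,T,T
G18,M,M,HT
G19,S,S,M
G20,S,T,T
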