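participant,whole_head_artificial,whole_head_real,whole_head_pd,brain_artificial,brain_real,brain_pd
1,0.0227,0.0284,20.07,0.0191,0.0219,12.79
2,0.0225,0.0359,37.33,0.0215,0.0308,30.19
3,0.0349,0.0469,25.59,0.0256,0.0363,29.48
4,0.0243,0.0243,0.00,0.0206,0.0232,11.21
5,0.0211,0.0272,22.43,0.0215,0.0255,15.69
6,0.0244,0.0323,24.46,0.0234,0.028,16.43
7,0.0306,0.0293,4.44,0.0186,0.021,11.43
8,0.0227,0.0302,24.83,0.0186,0.0231,19.48
9,0.0236,0.0317,25.55,0.0191,0.0252,24.21
10,0.0314,0.0372,15.59,0.0242,0.031,21.94
11,0.0225,0.0264,14.77,0.0186,0.0219,15.07
12,0.0288,0.0284,1.41,0.022,0.0256,14.06
13,0.0306,0.0362,15.47,0.0223,0.0238,6.30
14,0.0304,0.0318,4.40,0.0189,0.0216,12.50
15,0.0237,0.036,34.17,0.0242,0.0283,14.49
16,0.0216,0.0327,33.94,0.0204,0.024,15.00
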