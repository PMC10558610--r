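country,yes,no,printed_yes_pct,printed_no_pct
Afghanistan,998,2723,27,73
Algeria,916,5899,13,87
Bahamas,161,1482,10,90
Bangladesh,536,7510,6.7,93.3
Ecuador,291,4285,6.4,93.6
Ethiopia,97,8791,1.1,98.9
Jordan,662,4865,12,88
Lesotho,62,2207,2.7,97.3
Liberia,30,2359,1.3,98.7
Marshall Islands,362,2594,12.1,87.8
Sudan,391,6904,5.4,94.6
Uganda,44,3737,1.2,98.8
Indonesia,778,34544,2.2,97.8
Ghana,87,4648,1.8,98.2
Mexico,986,4922,16.7,83.3
South Africa,370,3653,8.8,91.2
India,8060,58796,12.1,87.9
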