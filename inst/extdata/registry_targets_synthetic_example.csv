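"age_low","age_high","cases","person_years","p_gs_lt7","p_gs_7","p_gs_gt7","mortality_cases"
40,45,2438,1e+07,0.406779661016949,0.372881355932203,0.220338983050847,269
45,50,21553,1e+07,0.508506616257089,0.321361058601134,0.170132325141777,1822
50,55,34236,1e+07,0.508599508599509,0.319410319410319,0.171990171990172,3750
55,60,42919,1e+07,0.464859437751004,0.326305220883534,0.208835341365462,6793
60,65,53272,1e+07,0.439419795221843,0.33617747440273,0.224402730375427,10718
65,70,63499,1e+07,0.403802281368821,0.331558935361217,0.264638783269962,14692
70,75,72749,1e+07,0.386498516320475,0.363501483679525,0.25,18135
75,80,34263,1e+07,0.295412844036697,0.354128440366972,0.35045871559633,19400
80,85,21511,1e+07,0.210526315789474,0.31203007518797,0.477443609022556,19453
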