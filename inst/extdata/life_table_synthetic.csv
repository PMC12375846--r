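"age","mortality_rate"
35,0.00155084360544013
36,0.00162319851588889
37,0.00170252589440972
38,0.00178949764164784
39,0.00188485040583462
40,0.00198939182217718
41,0.00210400735350566
42,0.00222966779011831
43,0.00236743747234774
44,0.00251848330549333
45,0.00268408464347605
46,0.00286564412492982
47,0.00306469955351097
48,0.00328293692305156
49,0.00352220469787931
50,0.00378452946925801
51,0.00407213312055802
52,0.00438745164654534
53,0.00473315578618822
54,0.00511217364374038
55,0.00552771548970101
56,0.00598330095171477
57,0.00648278882571809
58,0.00703040975983127
59,0.007630802087828
60,0.00828905111569081
61,0.0090107321940085
62,0.00980195794103737
63,0.0106694300164044
64,0.0116204958839743
65,0.0126632110446597
66,0.0138064072662855
67,0.0150597673884118
68,0.0164339073357099
69,0.0179404660345436
70,0.0195922039943447
71,0.0214031113887661
72,0.0233885265520558
73,0.0255652658943125
74,0.027951766336002
75,0.0305682414681508
76,0.0334368527608879
77,0.0365818972704687
78,0.0400300134346515
79,0.0438104066995097
80,0.0479550968887316
81,0.0524991894106179
82,0.0574811725998945
83,0.0629432437128155
84,0.0689316663367257
85,0.0754971622413339
86,0.082695340990662
87,0.0905871709544749
88,0.0992394957086428
89,0.108725600198332
90,0.119125831459409
91,0.13052827915556
92,0.143029521695236
93,0.156735444248037
94,0.171762135589092
95,0.188236871367692
96,0.206299192128424
97,0.226102085215631
98,0.247813280571873
99,0.271616671405781
100,0.297713871762317
101,0.32632592418802
102,0.357695171955092
103,0.392087311702046
104,0.429793643876696
105,0.471133540042675
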