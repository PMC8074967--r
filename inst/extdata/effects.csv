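effect,se
0.990772095303359,0.374617082516264
0.409784180879755,0.12781176060832
0.366848338705758,0.178257381767856
0.835509810078335,0.0659472389214937
0.303051169366556,0.127215093532603
0.553168164638083,0.128887509234751
0.815064692795528,0.367940434493179
0.503319961124213,0.128478254839222
0.48919589618184,0.0907706594932589
0.8938737026311,0.370789069844961
0.0424388000042988,0.250028139849826
0.511409914198816,0.0642710669755094
0.123611576647292,0.250238633325166
0.0312291428114772,0.353574940327382
0.420281061438506,0.0904247541915591
0.54167623976723,0.0643949266197593
0.778723330873846,0.366708544565011
0.652169789179866,0.091789571487827
0.319917472316459,0.251594092567357
0.588133642350041,0.36111591761822
0.0725550555202786,0.0894721422347847
0.652589310688513,0.362841925129441
0.0427345545935247,0.0632527716474002
0.263313684530897,0.0635190290246208
0.927855799239944,0.372091142736376
0.150755638120055,0.0633353268817055
0.881888494435861,0.261870186659499
0.479428937993763,0.128295378767794
0.211543522050727,0.126844398076711
0.728472872867514,0.182545721225959
0.447574651458109,0.178976288895562
0.900795472974675,0.262372476228507
0.664840548343313,0.181594639525457
0.431907450429233,0.12795736825784
0.521032540398148,0.254206407708286
0.673029374529603,0.0650114164550339
0.332082249683384,0.0636799757402387
0.35862457593708,0.356384000817281
0.213247365923849,0.0896965687140454
0.258857762595595,0.0898165204250087
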