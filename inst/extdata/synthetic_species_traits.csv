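"species","log_rate","genome_size","gc","pin_pis","lab_dt","mutation_rate","rrn_copies","trna_count","lifestyle"
"sp01",-6.71753163733586,3.15202201796256,47.7742471053461,0.10936679806123,5.86732939791013,2.05737297841189e-10,2,49,"opportunistic"
"sp02",-5.85212065227521,2.76185123896503,34.9931595694568,0.0497173176958681,3.84397060508963,2.472269837268e-10,5,67,"opportunistic"
"sp03",-4.77977152794955,0.727169139261178,22.0084632180177,0.02855088613647,13.3377181827081,3.60223309535899e-10,3,57,"obligate"
"sp04",-6.81625459260012,3.11349139484434,48.3905169999897,0.131318590662235,5.49414646922817,2.44113103043691e-10,3,49,"obligate"
"sp05",-5.43935681447671,1.57653947103601,29.9406402443531,0.0742560727061483,4.53445381150716,2.84323227420467e-10,4,46,"obligate"
"sp06",-5.6474136113046,2.32362598392295,36.5267890081444,0.139414803130595,4.94292929713675,1.889423993135e-10,4,53,"opportunistic"
"sp07",-5.266466870016,1.87704868502572,31.8009269847865,0.0570973035157839,2.45027173887825,2.94854535590498e-10,2,38,"opportunistic"
"sp08",-5.72664306404585,1.03897861933403,26.6968835403352,0.059886681563448,6.87310823252932,5.04229853332128e-10,3,50,"opportunistic"
"sp09",-4.17496559685963,0.5,29.2495814729214,0.0340922357723241,5.48849969303785,3.8924961968701e-10,4,48,"obligate"
"sp10",-5.11585695281845,2.85863746889757,39.592505375883,0.050024290506069,2.08450299986415,4.39812898053904e-11,4,67,"opportunistic"
"sp11",-5.14262625371505,1.84473757906365,35.0921386681169,0.0810572460622214,4.60164008988553,1.06920143327405e-10,4,65,"obligate"
"sp12",-4.54267290093182,2.84524338765838,25.274662874871,0.0573022761555982,3.69591355008156,4.88466336686056e-11,4,54,"opportunistic"
"sp13",-4.9919129640739,1.00135715758393,28.9706090723907,0.0474686194797685,7.43557275201114,3.54784228892836e-10,4,44,"obligate"
"sp14",-5.90077503260565,2.2589903742306,27.4602119899507,0.0655406642481562,2.8476604708923,3.06929690467821e-10,4,64,"obligate"
"sp15",-4.00767660870693,1.04407276758247,22.0841952406439,0.0603691880524001,5.80506254787236,2.4156747110977e-10,6,64,"opportunistic"
"sp16",-6.05444879134939,1.67442049552186,30.0213116425455,0.107196075156524,7.44879146622228,4.80442169859015e-10,6,62,"obligate"
"sp17",-4.35249269875464,1.46544803206967,20,0.0379468731531638,7.2753675103498,2.00581059686774e-10,2,62,"opportunistic"
"sp18",-4.59419857295346,3.17027826400306,33.8442326710807,0.0472698649382562,2.01491756189522,4.83206935676775e-11,5,51,"opportunistic"
"sp19",-5.00884921554311,1.21182597926663,26.1351937750653,0.0918071196896049,8.33329279861018,2.13454603924027e-10,6,62,"opportunistic"
"sp20",-4.45862260703971,2.35170503749995,27.7845794182085,0.050004690834218,1.65234345766852,1.76141310461028e-10,3,68,"obligate"
"sp21",-3.98464137518402,1.9115582609367,20,0.0638634575220284,4.48580806006048,6.82506974850885e-11,3,55,"obligate"
"sp22",-4.77770199235374,1.6867356056972,24.740863875602,0.0615680883719601,6.98260556770244,1.13389787650906e-10,1,45,"opportunistic"
"sp23",-4.86530273904226,1.43003282078956,35.6562596774041,0.0575114227321419,3.35855512604286,1.22449603386835e-10,2,63,"obligate"
"sp24",-4.54568231172322,1.99009436107023,37.1428341112551,0.0773041058556237,2.78770586991319,9.4312667405924e-11,2,63,"opportunistic"
"sp25",-4.96875087695376,1.26580742305666,27.1107823287002,0.0388313707856967,7.77982013939733,3.3723459428521e-10,3,52,"opportunistic"
"sp26",-6.3419467807646,3.55242314923626,36.6655163200398,0.0605440575117725,3.6384632825221,2.09948632176403e-10,5,72,"obligate"
"sp27",-4.63886573256859,0.5,20,0.0184195742855369,8.50534462801666,6.45548173864143e-10,4,47,"opportunistic"
"sp28",-4.65744838513542,2.87669484844667,24.9460747736822,0.0261558762112662,4.1286570397711,5.98113410490484e-11,6,58,"opportunistic"
"sp29",-5.62115308508868,1.85796806032089,31.1777791747399,0.082066049951409,1.94812718015647,3.04929071724846e-10,4,32,"obligate"
"sp30",-4.41543705443832,2.28878096245882,27.4483412787366,0.051358482173263,1.44504669560806,1.64318516210041e-10,5,53,"obligate"
"sp31",-4.00762472980749,2.08537898051624,20,0.0630841886632316,6.04995073007946,6.00339074518601e-11,3,66,"opportunistic"
"sp32",-5.22468185348743,1.4353840654193,29.6304525441403,0.0364356121939547,1.71790694136158,2.88947774747952e-10,3,50,"obligate"
"sp33",-4.24900172090626,0.5,24.6085689241176,0.0717949378058802,3.2658306924901,2.7401350245937e-09,2,46,"obligate"
"sp34",-5.24692929510456,1.40480233606506,30.5397291413307,0.114752250128991,9.28199210265751,2.35231428492961e-10,4,62,"obligate"
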