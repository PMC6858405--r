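"species","rate","sampling_time","site_class","hypermutator","study"
"sp01",1.22987284232985e-07,1.0676100749865,"all",FALSE,"sp01_study1"
"sp01",4.75980196390961e-07,8.56926974909625,"all",FALSE,"sp01_study2"
"sp01",7.02487800924007e-08,7.60270570033085,"all",FALSE,"sp01_study3"
"sp01",1.29698923628943e-07,383.694834586976,"all",FALSE,"sp01_study4"
"sp02",5.2100430194896e-06,20.8932565152191,"all",FALSE,"sp02_study1"
"sp02",4.79665311052019e-06,27.8898905905032,"all",FALSE,"sp02_study2"
"sp03",2.1634440771531e-05,1463.30003621508,"all",FALSE,"sp03_study1"
"sp03",1.60948649629801e-05,40.5473580562589,"all",FALSE,"sp03_study2"
"sp03",1.70033323724751e-05,35.9835855733393,"all",FALSE,"sp03_study3"
"sp04",1.4807584110883e-07,5.74015267690832,"all",FALSE,"sp04_study1"
"sp04",1.42440954301626e-07,614.60375852366,"all",FALSE,"sp04_study2"
"sp04",1.25519741661887e-07,119.90068310772,"all",FALSE,"sp04_study3"
"sp05",1.93668947722309e-06,5.87702434641961,"all",FALSE,"sp05_study1"
"sp05",1.40479015850114e-06,62.571972179027,"all",FALSE,"sp05_study2"
"sp06",2.52080385013636e-06,198.383159075856,"all",FALSE,"sp06_study1"
"sp07",1.01504401624977e-05,698.133955649242,"all",FALSE,"sp07_study1"
"sp07",2.85183699454653e-06,371.280032502053,"all",FALSE,"sp07_study2"
"sp08",6.81330662436534e-07,229.560317849226,"all",FALSE,"sp08_study1"
"sp08",4.81445260504267e-06,60.4973024645359,"all",FALSE,"sp08_study2"
"sp09",0.000121164101157045,1.65810034489314,"all",FALSE,"sp09_study1"
"sp09",5.05450294490334e-05,43.1740922336819,"all",FALSE,"sp09_study2"
"sp10",1.07848366144555e-05,12.5301388529505,"all",FALSE,"sp10_study1"
"sp10",6.91613363044899e-06,416.746016010778,"all",FALSE,"sp10_study2"
"sp11",8.16270989196226e-06,779.40538360966,"all",FALSE,"sp11_study1"
"sp11",1.75843956648914e-05,178.805984649012,"all",FALSE,"sp11_study2"
"sp12",1.30266812756145e-05,1382.12099116927,"all",FALSE,"sp12_study1"
"sp12",1.88624930038573e-05,4.50524959631705,"all",FALSE,"sp12_study2"
"sp12",1.10645394605284e-05,892.825430638738,"all",FALSE,"sp12_study3"
"sp12",2.60282853456411e-05,4.14119626459861,"all",FALSE,"sp12_study4"
"sp13",9.64267004817212e-06,6.38128904734328,"all",FALSE,"sp13_study1"
"sp13",1.37649445034645e-05,99.94620044627,"all",FALSE,"sp13_study2"
"sp13",3.97518483408571e-05,7.0165268751382,"all",FALSE,"sp13_study3"
"sp13",6.74620344687278e-06,49.1017272280543,"all",FALSE,"sp13_study4"
"sp14",1.28017783062731e-06,36.7952281738547,"all",FALSE,"sp14_study1"
"sp14",2.19838661846176e-06,253.271838540322,"all",FALSE,"sp14_study2"
"sp15",0.000204955046097063,2.83821311949821,"all",FALSE,"sp15_study1"
"sp15",3.96740797458907e-05,17.7188294869692,"all",FALSE,"sp15_study2"
"sp16",9.6597550064219e-07,4.33635512642866,"all",FALSE,"sp16_study1"
"sp17",3.37520879739982e-05,3.95552653989486,"all",FALSE,"sp17_study1"
"sp18",3.66144183071002e-05,631.181871024084,"all",FALSE,"sp18_study1"
"sp19",3.0032928502373e-05,1.09825841275944,"all",FALSE,"sp19_study1"
"sp19",8.83435754043424e-06,61.4130899731775,"all",FALSE,"sp19_study2"
"sp19",3.77897507840259e-05,134.960057492764,"all",FALSE,"sp19_study3"
"sp19",8.87528714668348e-06,9.90899479817186,"all",FALSE,"sp19_study4"
"sp20",2.19584033974904e-05,76.9517191793331,"all",FALSE,"sp20_study1"
"sp20",2.0060194521353e-05,1132.3507001622,"all",FALSE,"sp20_study2"
"sp21",0.000252021228826677,300.158426155469,"all",FALSE,"sp21_study1"
"sp22",8.36880450461614e-06,11.5123666517408,"all",FALSE,"sp22_study1"
"sp22",2.67069665157639e-05,7.90645445320292,"all",FALSE,"sp22_study2"
"sp22",2.0289025272498e-05,1.69583020571315,"all",FALSE,"sp22_study3"
"sp22",1.67800313687286e-05,1.67684915285957,"all",FALSE,"sp22_study4"
"sp23",5.6415610229326e-06,110.892417906139,"all",FALSE,"sp23_study1"
"sp23",7.85766513377411e-06,5.82845658802569,"all",FALSE,"sp23_study2"
"sp23",1.52202570740404e-05,21.5809531438809,"all",FALSE,"sp23_study3"
"sp23",2.08514639191084e-05,187.181783090373,"all",FALSE,"sp23_study4"
"sp24",1.71808594928918e-05,1102.84702889489,"all",FALSE,"sp24_study1"
"sp24",4.12130568008901e-05,33.763724519989,"all",FALSE,"sp24_study2"
"sp24",2.68211070689382e-05,773.816633455456,"all",FALSE,"sp24_study3"
"sp24",1.1459402194684e-05,1395.29227920642,"all",FALSE,"sp24_study4"
"sp25",9.98889943361089e-06,27.7018918118244,"all",FALSE,"sp25_study1"
"sp25",1.10844451856467e-05,13.9959959555087,"all",FALSE,"sp25_study2"
"sp25",3.26134808308025e-06,13.9878410726157,"all",FALSE,"sp25_study3"
"sp25",3.14764125733967e-05,1.56414440444388,"all",FALSE,"sp25_study4"
"sp26",6.10085246174126e-07,239.630312773333,"all",FALSE,"sp26_study1"
"sp26",5.90121405671187e-07,2.70346855640486,"all",FALSE,"sp26_study2"
"sp26",3.10404478558592e-07,3.62856063214895,"all",FALSE,"sp26_study3"
"sp26",4.94206268576713e-07,1.35947589717481,"all",FALSE,"sp26_study4"
"sp27",1.32379690501305e-05,27.7896066971579,"all",FALSE,"sp27_study1"
"sp27",1.51312599587664e-05,1199.86749784973,"all",FALSE,"sp27_study2"
"sp27",7.50995691698198e-05,128.591216409183,"all",FALSE,"sp27_study3"
"sp27",1.40071501495446e-05,472.334814905066,"all",FALSE,"sp27_study4"
"sp28",8.02933633209876e-05,14.1786005061971,"all",FALSE,"sp28_study1"
"sp28",1.74315130453308e-05,3.19215622680117,"all",FALSE,"sp28_study2"
"sp28",4.31055014321599e-05,92.8441494574667,"all",FALSE,"sp28_study3"
"sp29",1.24873398760422e-06,2.0210373434166,"all",FALSE,"sp29_study1"
"sp30",8.66075795475128e-05,84.764193356236,"all",FALSE,"sp30_study1"
"sp30",1.65017817252648e-05,7.5330313593588,"all",FALSE,"sp30_study2"
"sp30",1.69987774309759e-05,1488.24150168964,"all",FALSE,"sp30_study3"
"sp30",6.44031859338529e-06,1.06494296935633,"all",FALSE,"sp30_study4"
"sp31",0.000191936857962268,7.71330841261443,"all",FALSE,"sp31_study1"
"sp31",0.000143900720351718,835.169941949263,"all",FALSE,"sp31_study2"
"sp32",1.37752780784602e-05,601.402155650752,"all",FALSE,"sp32_study1"
"sp32",1.18978395477398e-05,1.40811664110646,"all",FALSE,"sp32_study2"
"sp32",9.79753545467274e-06,830.08184272736,"all",FALSE,"sp32_study3"
"sp33",8.66151568539111e-05,2.11195413297206,"all",FALSE,"sp33_study1"
"sp34",2.47981275725805e-06,24.6623889946883,"all",FALSE,"sp34_study1"
"sp34",7.41672905452907e-06,10.8925874469301,"all",FALSE,"sp34_study2"
"sp34",3.96421966989153e-06,1.09296394870002,"all",FALSE,"sp34_study3"
"sp05",1.93668947722309e-06,5.87702434641961,"all",TRUE,"sp05_study1_flagged"
"sp23",5.6415610229326e-06,110.892417906139,"synonymous",FALSE,"sp23_study1_flagged"
"sp30",8.66075795475128e-05,84.764193356236,"synonymous",FALSE,"sp30_study1_flagged"
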