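E_n_MeV,region,species,dose_fraction,dose_fraction_err,yD_keV_um,yD_err
0.0001,outer,electron,0.90579030851778153,0.027173709255533446,2,0.059999999999999998
0.0001,outer,proton,0.090577545411928612,0.0027857572509739719,54.590170723724718,1.6377051217117415
0.0001,outer,deuteron,0.003624952468077237,0.00032043134585023927,14.992391654038805,0.44977174962116412
0.0001,outer,C,1.2206976183705219e-06,1.2206454663684415e-07,0.032250623404762827,0.00096751870214288474
0.0001,outer,N,3.2300010594165184e-06,3.2296359371614098e-07,0.028260751133702421,0.00084782253401107259
0.0001,outer,O,2.7429035348595609e-06,2.7426402297224342e-07,0.025160747174879001,0.00075482241524636999
0.001,outer,electron,0.90571447281858974,0.02717143418455769,2,0.059999999999999998
0.001,outer,proton,0.090561797257384974,0.0027853268035426117,54.589344747755817,1.6376803424326745
0.001,outer,deuteron,0.0036361055454269221,0.00032129885751749665,14.947299232617613,0.44841897697852839
0.001,outer,C,1.487674642825922e-05,1.486900319301975e-06,0.32250623404762824,0.0096751870214288466
0.001,outer,N,3.9327569072171017e-05,3.9273489241184428e-06,0.28260751133702372,0.0084782253401107111
0.001,outer,O,3.3420063097952931e-05,3.3381004219184781e-06,0.25160747174878956,0.0075482241524636867
0.01,outer,electron,0.9046362939668684,0.027139088819006053,2,0.059999999999999998
0.01,outer,proton,0.090591606489605306,0.0027861416052193002,54.489736043977942,1.6346920813193382
0.01,outer,deuteron,0.0037166933152298909,0.00032754757885363568,14.864235084439137,0.44592705253317411
0.01,outer,C,0.00018028120739613823,1.7914877299906507e-05,3.2250623404762764,0.096751870214288285
0.01,outer,N,0.00047128533949843105,4.6360237127258486e-05,2.8260751133702384,0.084782253401107149
0.01,outer,O,0.00040383968140185721,3.9818889658251661e-05,2.5160747174878919,0.075482241524636756
0.10000000000000001,outer,electron,0.86852565419394046,0.026055769625818213,2,0.059999999999999998
0.10000000000000001,outer,proton,0.11663206854741641,0.0035229108052436567,58.55563826151532,1.7566691478454595
0.10000000000000001,outer,deuteron,0.0041802669053815989,0.00036283424417539798,22.210534023386639,0.66631602070159912
0.10000000000000001,outer,C,0.001935463480624292,0.0001810497030825388,32.218167374521393,0.96654502123564179
0.10000000000000001,outer,N,0.0045198974416328702,0.00038799049797971644,28.260751133702389,0.84782253401107166
0.10000000000000001,outer,O,0.0042066494310044056,0.00036480920179431488,25.160747174878932,0.75482241524636795
1,outer,electron,0.18725667166160814,0.0056188255536548217,2,0.059999999999999998
1,outer,proton,0.78525911545592109,0.023557773463677632,42.999091688852992,1.2899727506655898
1,outer,deuteron,0.0032515713273207278,0.00029100409628415115,51.886373297638869,1.5565911989291661
1,outer,C,0.0054206784042325007,0.00045198345079716933,217.87888587527743,6.536366576258323
1,outer,N,0.0084613812498944476,0.00064181554655101756,202.64025319308789,6.0792075957926368
1,outer,O,0.010350581901023094,0.00074233747978867442,188.41997406300598,5.6525992218901795
10,outer,electron,0.10957919494218039,0.0033193901593514558,2,0.059999999999999998
10,outer,proton,0.75130005667184119,0.022539001700155239,10.421093735606943,0.31263281206820831
10,outer,deuteron,0.0076208686027251721,0.00059305885540763647,17.645872509125827,0.52937617527377478
10,outer,alpha,0.04114730544402017,0.0016024947860172327,139.01034620234384,4.170310386070315
10,outer,C,0.0057844694722786975,0.0004767509921742751,778.77059232039096,23.363117769611726
10,outer,N,0.049382064007150034,0.0017741124959869197,846.55634813336826,25.396690444001045
10,outer,O,0.035186040859804389,0.0014796275211905127,877.52172414425456,26.325651724327635
100,outer,electron,0.28550426257539979,0.0085651404974070519,2,0.059999999999999998
100,outer,proton,0.53201902525249778,0.015960570757679256,1.9588256854588919,0.058764770563766756
100,outer,deuteron,0.010457116233296438,0.00074766037828194866,3.5767309918396646,0.10730192975518993
100,outer,alpha,0.041289945093334925,0.0016054250944269454,39.539833386629013,1.1861950015988703
100,outer,C,0.036468201129895017,0.0015062531221692185,577.78816007487694,17.333644802246308
100,outer,N,0.044048611473163503,0.0016622797142903836,798.0735635247654,23.94220690574296
100,outer,O,0.050212838242412461,0.0017918514707407573,1024.6130224754404,30.738390674263211
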