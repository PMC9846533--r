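"name","space","x_mm","y_mm","z_mm","region"
"p1","fixed",1.4,1.175,1.225,"C"
"p2","fixed",0.875,1.125,1.2,"C"
"p3","fixed",1.4,0.825,1.19,"C"
"p4","fixed",1.525,1.315,1.3,"C"
"p5","fixed",0.875,1.425,1.27,"C"
"p6","fixed",0.765,0.96,1.255,"C"
"p7","fixed",1.5,1.3,1.5,"C"
"p8","fixed",1.65,1.7,1.25,"C"
"p9","fixed",1.7,1.4,1.3,"C"
"p10","fixed",1.5,1.45,0.85,"C"
"p11","fixed",1.3,1.45,1.15,"C"
"p12","fixed",0.65,1,0.85,"C"
"p13","fixed",0.95,0.95,1.25,"C"
"p14","fixed",1.25,1.25,1.5,"C"
"p15","fixed",1.2,1.3,1.25,"C"
"p16","fixed",1.55,1.3,1.3,"C"
"p17","fixed",0.8,1.15,1.15,"C"
"p18","fixed",0.15,1.25,0.95,"BS"
"p19","fixed",1.45,1.4,0.9,"C"
"p20","fixed",1.2,1.2,0.85,"C"
"p21","fixed",0.8,0.8,1.25,"C"
"p22","fixed",0.2,1.25,0.85,"BS"
"p23","fixed",2.1,1.4,1.2,"OB"
"p24","fixed",1.05,1.5,1.2,"C"
"p1","moving",1.48685638901578,1.22148003031008,1.24424537668928,"C"
"p2","moving",0.535369785463501,1.07133390065815,1.19657772504058,"C"
"p3","moving",1.52271116246565,0.739433994268418,1.19829925927984,"C"
"p4","moving",1.7062436220935,1.44123032685259,1.34451677977836,"C"
"p5","moving",0.53151094156585,1.46075734472002,1.28219151989011,"C"
"p6","moving",0.377685337409486,0.844996838374287,1.26045130249855,"C"
"p7","moving",1.66214379562241,1.41001702752389,1.59448378380585,"C"
"p8","moving",1.87580503194571,1.98537527907786,1.2773335295604,"C"
"p9","moving",2.02030545722709,1.60037638760844,1.35125441009668,"C"
"p10","moving",1.6333321221311,1.61063418289512,0.773046406513809,"C"
"p11","moving",1.27988758220562,1.5739779500241,1.14653766213349,"C"
"p12","moving",0.168504544276401,0.881394836935654,0.760517500887998,"C"
"p13","moving",0.70104323274303,0.855130942660685,1.26014224834655,"C"
"p14","moving",1.22088699346509,1.29498493570482,1.57743711913696,"C"
"p15","moving",1.1106624284866,1.35409393414472,1.26854243996064,"C"
"p16","moving",1.75435496349887,1.42563830443305,1.34588536124838,"C"
"p17","moving",0.396518743104133,1.092915585573,1.13239066081329,"C"
"p18","moving",-0.60741475337854,1.14687965283049,0.866050769727173,"BS"
"p19","moving",1.54988297040414,1.53491341875924,0.834865570919781,"C"
"p20","moving",1.11300812797401,1.21755792829739,0.775340909442919,"C"
"p21","moving",0.478032280926891,0.64496296745767,1.25525525032816,"C"
"p22","moving",-0.535963199885474,1.15193312357781,0.745646085999517,"BS"
"p23","moving",2.75743568139191,1.68043146845111,1.22490601160221,"OB"
"p24","moving",0.835380864495761,1.58796561365895,1.2016991714572,"C"
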