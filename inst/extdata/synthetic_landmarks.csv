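"name","space","x_mm","y_mm","z_mm"
"OB","fixed",2.325,0.965,1.2
"OB","fixed",2.325,1.385,1.2
"OB","fixed",2.075,0.875,1.26
"OB","fixed",2.075,1.475,1.26
"vessel","fixed",1.4,1.175,1.225
"vessel","fixed",0.875,1.125,1.2
"vessel","fixed",1.4,0.825,1.19
"CB","fixed",0.45,0.9,1.46
"CB","fixed",0.45,1.45,1.46
"CB","fixed",0.3,1.175,1.285
"DG","fixed",1.475,0.9,1.375
"DG","fixed",1.475,1.45,1.375
"HC","fixed",1.185,0.84,1.175
"HC","fixed",1.185,1.51,1.175
"BS","fixed",0.0499999999999998,1.175,0.815
"BS","fixed",0.425,1.275,0.915
"C","fixed",1.575,1.175,1.475
"C","fixed",1.175,0.725,1.025
"OB","moving",3.17487035474841,1.03956668416484,1.22448128241089
"OB","moving",3.13007762626479,1.68013254493659,1.22448128241089
"OB","moving",2.75319147330756,0.873654427941787,1.30563068830401
"OB","moving",2.68961526500836,1.78283656469589,1.30563068830401
"vessel","moving",1.48685638901578,1.22148003031008,1.24424537668928
"vessel","moving",0.535369785463501,1.07133390065815,1.19657772504058
"vessel","moving",1.52271116246565,0.739433994268418,1.19829925927984
"CB","moving",-0.0712670022016373,0.735469778284386,1.5016349169874
"CB","moving",-0.120447372738613,1.4387818437151,1.5016349169874
"CB","moving",-0.378146065660047,1.06698620916022,1.28219080760928
"DG","moving",1.65432209664931,0.849702863685872,1.43434618884522
"DG","moving",1.60094536314835,1.61302571535664,1.43434618884522
"HC","moving",1.13533191557962,0.738741130181998,1.17465775751297
"HC","moving",1.07316555504918,1.62776150452228,1.17465775751297
"BS","moving",-0.714822924138667,1.04298728920611,0.703936357473952
"BS","moving",-0.227047546936731,1.20639965562635,0.829393682655462
"C","moving",1.811944319581,1.24979739262583,1.57089589177936
"C","moving",1.13547876628969,0.587881981150117,0.991713924431208
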