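CpG,Coefficient
(Intercept),-0.4
cg22236758,0.00139421
cg20578377,0.172389
cg24581794,-0.984208
cg77907146,-0.198682
cg90073223,-1.62855
cg46988649,-2.54145
cg95764131,0.471501
cg95201369,0.0734404
cg06280202,-0.293675
cg43078136,-2.62801
cg10906478,1.26215
cg34852405,0.0997622
cg52406988,0.403525
cg76566611,0.293787
cg85792989,0.59053
cg16020584,-1.50006
cg18160810,1.36702
cg41870769,1.04692
cg68430090,0.639487
cg88688382,-0.440778
cg85583560,0.0750821
cg36799849,1.91924
cg03015062,0.539506
cg59005622,0.360389
cg58399480,0.724569
cg01819708,-1.05939
cg97946019,0.778972
cg67346498,-1.24891
cg39452836,0.478472
cg73215842,-1.31204
cg83525173,-0.817494
cg26488900,-0.0969989
cg14034403,-1.69095
cg63148939,-0.570884
cg82815232,1.31608
cg26796642,-1.44632
cg00280624,-0.188527
cg17183244,0.131245
cg54435925,0.383612
cg44186389,1.4335
cg66529264,0.162708
cg17651442,0.114209
cg79603245,0.640607
cg68624683,-0.136608
cg58826305,-0.642879
cg59062222,-0.420212
cg83293220,0.967186
cg05664423,0.0198478
cg69801532,-0.387591
cg72490198,0.365493
cg77333891,-1.40117
cg96074894,-0.592668
cg05163959,2.00007
cg21724522,-0.187903
cg82183787,-1.48029
cg07243010,1.02256
cg85465416,-0.723341
cg36312764,-0.815913
cg68055957,-0.747064
cg27606160,-0.879595
cg95853463,-1.15667
cg41487657,1.44945
cg11711950,-0.611063
cg28844519,-0.125595
cg06816911,-0.318838
cg59696401,1.05258
cg78168764,0.496891
cg34021130,0.513958
cg89765222,-0.275989
cg65102332,-0.682819
cg25935845,0.075638
cg90019379,-0.241378
cg57270184,0.507202
cg74908798,-2.98692
cg94759471,0.835987
cg09991048,0.592757
cg27659032,1.21383
cg82278034,-2.00148
cg84568909,-0.794924
cg13403333,-0.074758
cg82746126,-1.41352
cg36218113,-0.660563
cg18385949,0.707579
cg01077559,-1.19242
cg61800164,0.309147
cg49763568,-0.939025
cg87467323,1.18883
cg22080384,0.656888
cg15071952,0.540722
cg84104329,-0.00555469
cg90638946,-0.851365
cg06398515,0.331131
cg37254693,0.671961
cg77791411,0.763468
cg20059954,-0.329015
cg55691684,-0.179295
cg31190365,-1.1134
cg52114980,-1.09757
cg29800632,0.308812
cg76630854,-0.432251
cg82454250,-0.164861
cg38564579,-1.45707
cg80669339,-2.4018
cg32345338,-1.05468
cg57642260,1.58174
cg03573620,0.170565
cg78741465,-2.0509
cg68606895,-0.136925
cg06092242,0.106802
cg18364613,-0.791075
cg21776481,-1.28026
cg59482922,0.189607
cg26164006,-0.12579
cg48156108,-0.388467
cg79303876,0.524473
cg83313104,1.98561
cg88608283,0.254397
cg14029487,0.885387
cg70418304,-0.22508
cg91954473,0.449034
cg32542228,1.20809
cg46257179,-0.295559
cg14500569,-1.74507
cg81566611,0.0228314
cg91564708,-1.38117
cg68010227,0.950238
cg77783916,-0.61603
cg00724618,0.901155
cg01833569,-0.48475
cg61887132,1.15894
cg57688848,-1.98963
cg24562098,0.311823
cg02831913,-0.412999
cg60650844,-0.394554
cg96701792,-0.173641
cg63477836,-0.387879
cg18560785,-1.41206
cg01028459,0.458714
cg41679850,-0.189648
cg08842392,-1.26009
cg13488993,1.30345
cg91765690,-2.69905
cg13500489,1.3888
cg96472210,-1.08989
cg48918139,2.79023
cg63116795,-0.110838
cg87499427,0.739956
cg47314956,1.30927
cg25470491,-0.231619
cg38669713,0.682597
cg13761162,1.37426
cg81575470,0.229178
cg38777334,0.779023
cg77173490,0.83843
cg41345532,-0.0313917
cg02368979,-1.67198
cg50976754,0.317172
cg16167618,2.64742
cg30539532,0.865797
cg72279322,-1.53107
cg35759441,2.00054
cg79691286,0.299066
cg64557533,0.843625
cg99017740,1.10615
cg23458943,-0.779018
cg10365608,0.085769
cg46640934,1.21985
cg30456452,1.87607
cg65135536,-0.260887
cg24622367,1.20722
cg28453515,0.726919
cg83459674,1.03795
cg26588229,-0.588392
cg65073597,-0.200228
cg96082874,-0.0412233
cg44919230,0.266477
cg67633265,-1.44503
cg80088694,-0.108415
cg12995347,0.55943
cg48819648,-0.533457
cg00674288,1.28207
cg74654390,2.19038
cg78507237,0.622208
cg22193075,1.93761
cg56040835,-1.24136
cg90788667,1.10447
cg23335950,-0.574234
cg91709243,-0.568847
cg40371076,-0.0735143
cg95375839,-1.34536
cg12690593,-1.14903
cg37041816,-1.57876
cg48955829,1.51745
cg16093359,-0.552621
cg68319806,0.266803
cg72540570,-0.140557
cg11531923,-0.187969
cg07754824,-0.979791
cg97779305,-0.49037
cg47061116,2.16229
cg44003060,-1.28644
cg26351703,0.197267
cg16144088,0.865311
cg00957382,-1.0654
cg30067042,0.538724
cg96656781,0.187872
cg26498508,-1.69773
cg63190492,1.35885
cg10980842,-0.633954
cg12215298,-0.165416
cg06804781,0.147207
cg71244648,-0.920631
cg35555450,-0.125174
cg98530715,-0.874406
cg75975760,0.00310639
cg06334271,0.250184
cg42178294,-2.22721
cg27952105,1.76684
cg23796663,0.661374
cg13272578,0.214355
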