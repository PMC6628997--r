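CpG,Coefficient
(Intercept),30.1
cg18196621,1.69304
cg21240601,-0.66869
cg91369272,0.337994
cg14504782,-0.0798004
cg52634947,2.7116
cg74744409,-3.39676
cg63174117,-0.558486
cg57585756,0.838877
cg08841661,1.59574
cg52997382,-2.3348
cg85839673,-0.189399
cg01999984,1.72192
cg14563965,0.2873
cg86490924,-4.475
cg35142390,0.512847
cg33594764,-0.944113
cg99924937,-3.03149
cg31843677,0.352586
cg24991338,2.8836
cg32369872,-0.75534
cg41346118,0.0458996
cg65539715,0.444904
cg87959420,-1.42415
cg69619188,-1.12437
cg31787656,-1.93828
cg23453211,-1.29613
cg86296281,-0.0640242
cg82439410,0.451875
cg24606968,0.565105
cg97427326,4.28776
cg03314733,-1.95536
cg98316186,0.377593
cg25461561,1.79381
cg60645799,4.39084
cg07474992,0.568144
cg29462335,0.752805
cg35866904,1.9706
cg78754584,-2.30762
cg59709830,-1.04915
cg63993016,-1.5645
cg86842908,1.76827
cg99169293,2.81104
cg21339452,3.27827
cg27695690,-0.520702
cg40982213,3.2726
cg66313192,0.611203
cg82731616,-1.50987
cg83307221,0.664866
cg42358633,2.20124
cg06406430,0.688083
cg89338496,1.61416
cg00529428,-0.759005
cg15426705,0.84915
cg75868659,-3.71539
cg38224646,0.942497
cg05332165,1.20937
cg25569094,-1.295
cg90373098,4.81439
cg04312676,0.894555
cg24135322,3.5701
cg03349701,1.68816
cg13333429,0.199514
cg89358747,0.552789
cg40665092,2.55029
cg22515124,-1.14745
cg82796109,-0.445347
cg69011781,0.671369
cg80265466,0.792373
cg21552985,-3.65824
cg69023274,-0.0221798
cg20117927,-0.851679
cg04768448,0.280998
cg06969776,-3.77477
cg96162491,2.83968
cg98001665,-3.4063
cg58526725,0.774594
cg94036440,1.65231
cg57493003,-3.7768
cg01034252,2.58504
cg06702919,-1.50421
cg26643952,0.0999813
cg44530133,-0.762871
cg62739407,1.82532
cg85800872,0.189602
cg89387827,1.06758
cg07887366,2.70386
cg22494072,-1.27055
cg73327012,-5.20854
cg60976090,1.01631
cg61474561,0.860114
cg88314158,-1.15512
cg14260689,0.3753
cg37518233,-0.24713
cg50493638,0.236641
cg25743295,-1.69271
cg24149870,1.60553
cg34467020,-3.76345
cg63859148,1.48535
cg76661540,-0.441648
cg60867698,-2.26306
cg81615896,0.875756
cg90310109,-1.27721
cg55544386,2.21766
cg52149850,0.601369
cg17507170,-0.859857
cg24409626,-0.623709
cg03339795,-0.407054
cg00499037,-3.72262
cg80363917,-1.13512
cg14574077,0.150644
cg34526084,-1.07648
cg61366407,0.300189
cg81896591,0.661903
cg62450301,-4.29301
cg06537151,0.408015
cg90250445,0.510479
cg12885846,0.897632
cg29731088,-0.711865
cg94020969,2.20122
cg33802885,-1.6263
cg38531586,-1.13636
cg62080972,-1.27942
cg15383916,-0.314063
cg54749912,-3.23355
cg86875322,-2.44946
cg28563864,1.16672
cg34139464,1.71808
cg98288745,0.319482
cg33335392,2.54411
cg83517427,1.06764
cg72294282,-0.618239
cg37531155,1.8635
cg30270407,1.52382
cg16069320,1.43791
cg18984654,2.12182
cg92444255,-1.02458
cg49823870,1.00159
cg31479211,1.69712
cg35736012,3.13044
cg43688390,1.13409
cg99659368,0.718692
cg10711399,-0.764472
cg32658191,-0.179063
cg96563019,0.0724282
cg25030905,-3.53856
cg02308926,0.75153
cg80275142,3.89094
cg23122246,-1.68033
cg08158825,-0.754423
cg75316220,-1.15268
cg30549842,-2.45456
cg38372414,-2.76913
cg58877713,-4.39427
cg14735275,1.70297
cg25849019,0.511202
cg07855669,0.256221
cg26149404,-0.757045
cg51167765,2.5554
cg99086929,-4.13315
cg99632901,-0.651129
cg36956584,1.31224
cg37361439,1.69729
cg33798009,3.7313
cg63090496,0.311373
cg03130303,2.0848
cg88589504,0.0832756
cg86484860,-2.87254
cg56984419,0.439703
cg13924489,2.83072
cg74637505,-0.859723
cg80028392,-5.28041
cg13303782,-2.66546
cg42076846,2.9729
cg32734084,-0.290984
cg86811113,-0.554401
cg34325156,0.0483117
cg86222885,-1.25124
cg05473013,1.28215
cg67765857,2.75103
cg01298636,0.915753
cg69856244,2.46622
cg94612549,0.668869
cg66338542,-1.00676
cg67695055,2.99697
cg99867003,3.38684
cg84665282,-0.305293
cg36854450,-2.66401
cg85467638,0.870399
cg99491058,-1.22147
cg98727054,-1.11592
cg97127265,-1.50206
cg89446833,-2.62785
cg46179562,-2.50465
cg05502908,-1.52597
cg33234246,-4.86808
cg38964743,-3.06679
cg92646407,0.180324
cg81351444,0.214232
cg56779380,0.397032
cg25338488,2.55711
cg69105641,-2.36128
cg92740244,-2.53661
cg49710306,-0.205288
cg45255170,2.09007
cg15703805,1.25687
cg96583793,-0.199499
cg87608353,-1.43964
cg45178806,2.9383
cg34342174,-2.84918
cg92502892,-3.05924
cg60284366,0.693388
cg44175602,1.14496
cg03109328,1.53676
cg85280733,-0.0511858
cg83183717,1.27604
cg91768847,0.7966
cg47622179,-1.87807
cg31077793,-0.0866029
cg96460112,-2.53348
cg34871665,-4.10673
cg38198101,2.16124
cg02202327,-1.74477
cg03079224,-4.94109
cg34550968,0.609773
cg43400937,-1.70155
cg33151104,1.32114
cg56910581,-0.470284
cg87802398,-4.33539
cg43357143,-0.816147
cg56542475,-0.945651
cg32842320,2.2006
cg01990407,-1.00765
cg68357776,-1.35915
cg79385550,-0.713435
cg75765032,1.74738
cg52360937,4.35633
cg13229300,-0.919776
cg83700023,-0.801077
cg65985348,1.30406
cg50727460,2.87559
cg74990049,-0.10521
cg79009857,1.84092
cg99118480,-0.250568
cg80674121,-0.0706965
cg86539835,2.71151
cg52946871,3.83645
cg20390695,-3.14826
cg37178557,-2.83952
cg66043105,2.11204
cg26670442,-0.560345
cg33216846,-1.76184
cg56540599,-0.728439
cg99100945,2.02848
cg35800679,0.359874
cg16946905,1.46984
cg96545328,2.73216
cg05684710,2.98059
cg03110723,-1.74574
cg76610728,3.0671
cg09713273,-2.30576
cg31541329,-0.874466
cg15009279,1.15557
cg46600461,2.84507
cg18886994,-0.204193
cg81572276,-1.2163
cg55527468,-1.70758
cg90911443,2.19283
cg39833608,-2.65853
cg44583326,0.0898642
cg90207655,0.969863
cg93659673,-0.702602
cg56009940,-1.74289
cg53337704,-0.187012
cg44051106,2.15891
cg28415427,0.6515
cg84068484,-1.33674
cg83428819,-1.95081
cg96286779,1.50292
cg60293799,-1.30769
cg42443665,3.14658
cg72698422,-0.655033
cg71763359,-0.496665
cg11721447,3.82251
cg59428529,1.11708
cg19536666,1.79962
cg27744232,-2.02243
cg67162371,-2.31015
cg99222637,0.294926
cg13863856,-0.487559
cg67984487,0.676504
cg42863588,0.563362
cg78859267,1.65974
cg55769854,5.40261
cg89848013,-1.27911
cg46524968,2.27118
cg51703841,-2.44569
cg49313679,0.96113
cg02183118,-0.525417
cg81066296,-0.19295
cg48494339,0.6912
cg00396465,6.97431
cg25624549,0.640619
cg73848652,2.19679
cg29502282,0.792789
cg23847541,2.80843
cg77412982,0.45966
cg27931638,-0.765453
cg52147387,-0.319984
cg42218596,-3.05863
cg69149705,-1.76476
cg66939464,-0.353295
cg67828522,3.50778
cg90347151,3.68601
cg16384904,0.887474
cg49870991,0.643717
cg55244712,1.01465
cg93468635,-5.55317
cg55828664,0.14971
cg41972118,-1.68889
cg75896477,-1.57646
cg95304835,-1.01774
cg43640249,0.104471
cg79586657,2.06131
cg67242119,-1.61651
cg64921111,1.37493
cg32284342,-0.189638
cg10508616,6.96234
cg48394669,5.03509
cg27643244,-1.50468
cg41225369,1.60809
cg43046847,-2.2837
cg93475347,-1.48562
cg56374709,1.47083
cg06556120,-1.54572
cg94942266,-0.755609
cg18652467,-0.788103
cg14289387,-0.407992
cg77983438,-2.13621
cg66555328,1.19738
cg17174042,-2.15169
cg21261252,4.95772
cg08397863,-0.496553
cg68126508,3.30852
cg70425057,0.33561
cg02657082,-4.74137
cg65551976,-2.30224
cg17263509,1.32058
cg07131264,-1.76208
cg39846288,-0.299536
cg92111548,2.45964
cg03699475,-2.29095
cg12421809,2.04227
cg81484344,-0.692565
cg12005094,1.33334
cg72600425,-2.99037
cg18418437,-1.50277
cg29833985,1.4689
cg84956371,-3.19698
cg74407852,-1.18573
cg94225641,-2.13777
cg47190272,1.95562
cg85233517,-2.0004
cg88094650,-0.622852
cg17492402,2.06576
cg03826923,2.08183
cg47934588,3.84959
cg99233689,4.56307
cg82205666,0.780337
cg54593263,-1.89152
cg13181246,4.7584
cg96214179,-0.784645
cg29571919,0.946107
cg40188323,0.839183
cg93220550,-1.96969
cg71012853,-1.96984
cg42011277,1.04537
cg67365532,-2.6483
cg20214350,2.79098
cg72859045,0.953463
cg09234017,1.19069
cg11219365,-2.43439
cg16842545,-1.03396
cg89938433,0.280282
cg98946603,2.10079
cg61371998,-0.0121625
cg36136346,-0.266534
cg63051976,0.810607
cg76275608,1.3782
cg91698445,-0.0948515
cg91651408,0.160323
cg62504217,-1.27072
cg43069247,0.110517
cg52614529,0.31364
cg31252202,-0.511325
cg19164504,1.30408
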