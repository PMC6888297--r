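"time_min","readout","replicate","value"
30,"AMPK_T172P",1,0.000836509592419702
30,"p70S6K_P",1,1.01196562105361
30,"ULK1_S555P",1,3.73908545478249e-05
30,"LC3II",1,0.0929907962097831
30,"p62",1,1.08060527839477
30,"AMPK_T172P",2,0.000901891210691817
30,"p70S6K_P",2,0.809241202458297
30,"ULK1_S555P",2,3.25676506994267e-05
30,"LC3II",2,0.091271836316498
30,"p62",2,1.07899306969032
30,"AMPK_T172P",3,0.000873366735997429
30,"p70S6K_P",3,0.675777885030718
30,"ULK1_S555P",3,2.99392021778724e-05
30,"LC3II",3,0.0892411980387215
30,"p62",3,1.03116839701763
60,"AMPK_T172P",1,0.0251197748205011
60,"p70S6K_P",1,0.00633884724896922
60,"ULK1_S555P",1,0.0156912199919261
60,"LC3II",1,0.114434258524037
60,"p62",1,0.986885266454693
60,"AMPK_T172P",2,0.0299697692582524
60,"p70S6K_P",2,0.00689119549396124
60,"ULK1_S555P",2,0.0192999900916467
60,"LC3II",2,0.0995277387778222
60,"p62",2,1.04719765828721
60,"AMPK_T172P",3,0.0241364021223055
60,"p70S6K_P",3,0.00768244026969501
60,"ULK1_S555P",3,0.0147744072903595
60,"LC3II",3,0.103454211327317
60,"p62",3,1.06682315098433
90,"AMPK_T172P",1,0.0190301452517397
90,"p70S6K_P",1,0.00701243601620582
90,"ULK1_S555P",1,0.0250135833160139
90,"LC3II",1,0.135369145848432
90,"p62",1,0.99933168844309
90,"AMPK_T172P",2,0.0183864200682733
90,"p70S6K_P",2,0.00719677930056305
90,"ULK1_S555P",2,0.0286766034838757
90,"LC3II",2,0.138951347119714
90,"p62",2,1.04639978781648
90,"AMPK_T172P",3,0.0178787026287924
90,"p70S6K_P",3,0.00609911721191806
90,"ULK1_S555P",3,0.024676035753525
90,"LC3II",3,0.136689972312333
90,"p62",3,1.19550809637099
120,"AMPK_T172P",1,0.0150338918226763
120,"p70S6K_P",1,0.00763407482112172
120,"ULK1_S555P",1,0.0303478227300708
120,"LC3II",1,0.118311936246181
120,"p62",1,1.1837248941112
120,"AMPK_T172P",2,0.017321018850421
120,"p70S6K_P",2,0.00610527033493182
120,"ULK1_S555P",2,0.0302780103427551
120,"LC3II",2,0.136745289712034
120,"p62",2,1.11401105918585
120,"AMPK_T172P",3,0.0159797066652706
120,"p70S6K_P",3,0.00654886951312273
120,"ULK1_S555P",3,0.0317620163799566
120,"LC3II",3,0.129976859035033
120,"p62",3,1.18715247914349
150,"AMPK_T172P",1,0.0110968157812808
150,"p70S6K_P",1,0.00671659429625564
150,"ULK1_S555P",1,0.0311136883300484
150,"LC3II",1,0.129826147462196
150,"p62",1,0.979996521366703
150,"AMPK_T172P",2,0.0162640299773415
150,"p70S6K_P",2,0.00742806215350572
150,"ULK1_S555P",2,0.0325857821908802
150,"LC3II",2,0.142990084868912
150,"p62",2,1.21931363620087
150,"AMPK_T172P",3,0.014910430883156
150,"p70S6K_P",3,0.00610415001472454
150,"ULK1_S555P",3,0.0325726588927857
150,"LC3II",3,0.14080954272807
150,"p62",3,0.954061809433339
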