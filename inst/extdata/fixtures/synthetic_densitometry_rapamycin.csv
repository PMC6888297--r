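"time_min","readout","replicate","value"
0,"AMPK_T172P",1,0.0345047123021326
0,"p70S6K_P",1,0.0111959677692891
0,"ULK1_S555P",1,0.00120885702210827
0,"LC3II",1,0.0968587846239788
0,"p62",1,0.998375640085306
0,"AMPK_T172P",2,0.0306471010096063
0,"p70S6K_P",2,0.0103199835455773
0,"ULK1_S555P",2,0.00125589542549389
0,"LC3II",2,0.0938913753554561
0,"p62",2,1.21415061729961
0,"AMPK_T172P",3,0.0254425638407
0,"p70S6K_P",3,0.0119005049227231
0,"ULK1_S555P",3,0.00115687404343103
0,"LC3II",3,0.110236533043472
0,"p62",3,1.02431370080523
30,"AMPK_T172P",1,0.396589952017536
30,"p70S6K_P",1,0.00371069521197196
30,"ULK1_S555P",1,0.461977243375694
30,"LC3II",1,0.201478203188629
30,"p62",1,0.900286685379957
30,"AMPK_T172P",2,0.41825961382801
30,"p70S6K_P",2,0.00360222331801026
30,"ULK1_S555P",2,0.447894986873882
30,"LC3II",2,0.224729149230649
30,"p62",2,0.947360248322392
30,"AMPK_T172P",3,0.448673457775779
30,"p70S6K_P",3,0.00483661080061508
30,"ULK1_S555P",3,0.520156417668245
30,"LC3II",3,0.205811826219498
30,"p62",3,1.06322673376556
60,"AMPK_T172P",1,0.0481821236983897
60,"p70S6K_P",1,0.00575343048895395
60,"ULK1_S555P",1,0.548214439435907
60,"LC3II",1,0.537932041561219
60,"p62",1,0.758180716140293
60,"AMPK_T172P",2,0.0434161281077213
60,"p70S6K_P",2,0.00545002497054349
60,"ULK1_S555P",2,0.598568100292598
60,"LC3II",2,0.461256185935835
60,"p62",2,0.546901819786133
60,"AMPK_T172P",3,0.0445324206165451
60,"p70S6K_P",3,0.00592015780160566
60,"ULK1_S555P",3,0.557722748252958
60,"LC3II",3,0.452168771909882
60,"p62",3,0.679727240800217
90,"AMPK_T172P",1,0.0365965295827334
90,"p70S6K_P",1,0.00510956149923897
90,"ULK1_S555P",1,0.581440157228193
90,"LC3II",1,0.809017569070917
90,"p62",1,0.539461685532428
90,"AMPK_T172P",2,0.0448618666210536
90,"p70S6K_P",2,0.0053837064963877
90,"ULK1_S555P",2,0.67976384033143
90,"LC3II",2,0.685869596981009
90,"p62",2,0.523416897694174
90,"AMPK_T172P",3,0.0439204678019763
90,"p70S6K_P",3,0.00536051836156811
90,"ULK1_S555P",3,0.515036511918563
90,"LC3II",3,0.766411056413652
90,"p62",3,0.498096222967998
120,"AMPK_T172P",1,0.0348486061846933
120,"p70S6K_P",1,0.00500737018254281
120,"ULK1_S555P",1,0.488557783091627
120,"LC3II",1,0.962991337563497
120,"p62",1,0.196026370474166
120,"AMPK_T172P",2,0.0482570524838258
120,"p70S6K_P",2,0.00648378175093604
120,"ULK1_S555P",2,0.615323720665212
120,"LC3II",2,0.917023356749757
120,"p62",2,0.316432900329629
120,"AMPK_T172P",3,0.0370564059556259
120,"p70S6K_P",3,0.00528506187470103
120,"ULK1_S555P",3,0.546509685379392
120,"LC3II",3,0.936292496316762
120,"p62",3,0.207946601843978
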