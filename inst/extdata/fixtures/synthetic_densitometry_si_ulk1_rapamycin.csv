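"time_min","readout","replicate","value"
0,"AMPK_T172P",1,0.033123811040526
0,"p70S6K_P",1,0.0109573900083449
0,"ULK1_S555P",1,0.00128533145463851
0,"LC3II",1,0.124567055597348
0,"p62",1,1.13999745061194
0,"AMPK_T172P",2,0.0409866696782995
0,"p70S6K_P",2,0.0110665454075036
0,"ULK1_S555P",2,0.000873752153575943
0,"LC3II",2,0.104577575431089
0,"p62",2,1.02825805813711
0,"AMPK_T172P",3,0.0320717085939861
0,"p70S6K_P",3,0.00969414091689089
0,"ULK1_S555P",3,0.00102674877225738
0,"LC3II",3,0.0975311974624876
0,"p62",3,1.09200054386202
30,"AMPK_T172P",1,1.01676955569688
30,"p70S6K_P",1,0.00283702544829567
30,"ULK1_S555P",1,0.00108470486030036
30,"LC3II",1,0.110334128884983
30,"p62",1,1.15758528672577
30,"AMPK_T172P",2,1.00725122813143
30,"p70S6K_P",2,0.00340236801974263
30,"ULK1_S555P",2,0.000934048456447945
30,"LC3II",2,0.137154445779465
30,"p62",2,1.14935215672667
30,"AMPK_T172P",3,1.01213407149622
30,"p70S6K_P",3,0.00315963005063651
30,"ULK1_S555P",3,0.000921104983140734
30,"LC3II",3,0.105437673390967
30,"p62",3,1.07600315005444
60,"AMPK_T172P",1,0.879522692999746
60,"p70S6K_P",1,0.002858953810539
60,"ULK1_S555P",1,0.00086402877481098
60,"LC3II",1,0.133589851306101
60,"p62",1,1.02866256579349
60,"AMPK_T172P",2,1.07773171566746
60,"p70S6K_P",2,0.00365495154030097
60,"ULK1_S555P",2,0.000968192282952479
60,"LC3II",2,0.11137430021275
60,"p62",2,1.26954388208831
60,"AMPK_T172P",3,0.950378086000212
60,"p70S6K_P",3,0.00252207838813861
60,"ULK1_S555P",3,0.00103966284247382
60,"LC3II",3,0.0972744357894406
60,"p62",3,0.814787318466819
90,"AMPK_T172P",1,1.08571372406437
90,"p70S6K_P",1,0.00261342505323074
90,"ULK1_S555P",1,0.000828473464628867
90,"LC3II",1,0.0923471594257097
90,"p62",1,0.927383637886113
90,"AMPK_T172P",2,0.818727586209645
90,"p70S6K_P",2,0.00307382682246935
90,"ULK1_S555P",2,0.000976400122336152
90,"LC3II",2,0.126330552042462
90,"p62",2,1.08720184000633
90,"AMPK_T172P",3,0.965426089411378
90,"p70S6K_P",3,0.00292725202630768
90,"ULK1_S555P",3,0.00108159819196654
90,"LC3II",3,0.117170100669484
90,"p62",3,1.06330786855725
120,"AMPK_T172P",1,0.914558071020232
120,"p70S6K_P",1,0.00291005949526154
120,"ULK1_S555P",1,0.000965386998765123
120,"LC3II",1,0.104528092456128
120,"p62",1,0.977094572681431
120,"AMPK_T172P",2,1.04775367720161
120,"p70S6K_P",2,0.0032407494179161
120,"ULK1_S555P",2,0.00105516460781225
120,"LC3II",2,0.13940377637093
120,"p62",2,1.09289565123232
120,"AMPK_T172P",3,0.94521905732153
120,"p70S6K_P",3,0.00279550169298753
120,"ULK1_S555P",3,0.00103442009534046
120,"LC3II",3,0.0947599145003421
120,"p62",3,0.987583896120952
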