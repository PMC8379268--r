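"frame_index","timestamp_s","mean_r","mean_g","mean_b"
1,6,60.0610672790976,59.5130202075138,60.2751238660703
2,6.25,61.0054823552458,60.114586620624,60.3510372921438
3,6.5,59.6084626664261,59.8899422546906,60.0912261711749
4,6.75,59.4609120563257,60.2665831904773,60.1824221200944
5,7,59.677554499147,60.084437453385,58.7229959427632
6,7.25,60.0700752884296,60.0900045505666,60.4827543159353
7,7.5,59.9067408056121,59.5071395922718,60.1959163140939
8,7.75,60.0877728101297,60.0304340935201,59.9596720182683
9,8,59.3497285438463,60.5391728007962,58.4277555682318
10,8.25,59.9779316744788,59.2178792373572,59.8991850976339
11,8.5,59.8880823581568,59.7763411284328,60.4495097568165
12,8.75,59.8405186946861,60.5352668987286,59.669297784397
13,9,58.7292333886567,59.2539590362657,60.550099843872
14,9.25,60.6580788752142,60.7835363803917,60.324250790663
15,9.5,59.5364277923436,60.2323945197622,60.073226094618
16,9.75,59.515386415489,60.4203571073859,61.1143469956602
17,10,59.5181282165752,59.9141717988891,60.2454906959437
18,10.25,59.5048445829459,59.23721402408,60.4228306470886
19,10.5,60.0457935878794,60.0690790194764,60.9878237005289
20,10.75,59.9515053577887,60.5858173399829,60.0173983750923
21,11,60.1765400070689,60.1708401577461,59.9197394604105
22,11.25,60.0918042333004,59.9053568998165,60.082835166
23,11.5,59.7425096560649,59.408409714851,59.5824358905247
24,11.75,60.5774595243704,61.169169868581,59.3572911699597
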