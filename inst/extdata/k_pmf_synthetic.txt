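# synthetic K+ axial PMF: 3 kT wells at +/-9 A, 2.2 kT central barrier
# anchored feature values; curve between anchors is modelled
# temperature_K: 310
# bulk: right
-18 0
-17.9 -0.0336995885
-17.8 -0.0681152263
-17.7 -0.103222222
-17.6 -0.138995885
-17.5 -0.175411523
-17.4 -0.212444444
-17.3 -0.250069959
-17.2 -0.288263374
-17.1 -0.327
-17 -0.366255144
-16.9 -0.406004115
-16.8 -0.446222222
-16.7 -0.486884774
-16.6 -0.527967078
-16.5 -0.569444444
-16.4 -0.611292181
-16.3 -0.653485597
-16.2 -0.696
-16.1 -0.7388107
-16 -0.781893004
-15.9 -0.825222222
-15.8 -0.868773663
-15.7 -0.912522634
-15.6 -0.956444444
-15.5 -1.0005144
-15.4 -1.04470782
-15.3 -1.089
-15.2 -1.13336626
-15.1 -1.17778189
-15 -1.22222222
-14.9 -1.26666255
-14.8 -1.31107819
-14.7 -1.35544444
-14.6 -1.39973663
-14.5 -1.44393004
-14.4 -1.488
-14.3 -1.53192181
-14.2 -1.57567078
-14.1 -1.61922222
-14 -1.66255144
-13.9 -1.70563374
-13.8 -1.74844444
-13.7 -1.79095885
-13.6 -1.83315226
-13.5 -1.875
-13.4 -1.91647737
-13.3 -1.95755967
-13.2 -1.99822222
-13.1 -2.03844033
-13 -2.0781893
-12.9 -2.11744444
-12.8 -2.15618107
-12.7 -2.19437449
-12.6 -2.232
-12.5 -2.26903292
-12.4 -2.30544856
-12.3 -2.34122222
-12.2 -2.37632922
-12.1 -2.41074486
-12 -2.44444444
-11.9 -2.47740329
-11.8 -2.50959671
-11.7 -2.541
-11.6 -2.57158848
-11.5 -2.60133745
-11.4 -2.63022222
-11.3 -2.65821811
-11.2 -2.68530041
-11.1 -2.71144444
-11 -2.73662551
-10.9 -2.76081893
-10.8 -2.784
-10.7 -2.80614403
-10.6 -2.82722634
-10.5 -2.84722222
-10.4 -2.866107
-10.3 -2.88385597
-10.2 -2.90044444
-10.1 -2.91584774
-10 -2.93004115
-9.9 -2.943
-9.8 -2.95469959
-9.7 -2.96511523
-9.6 -2.97422222
-9.5 -2.98199588
-9.4 -2.98841152
-9.3 -2.99344444
-9.2 -2.99706996
-9.1 -2.99926337
-9 -3
-8.9 -2.99919122
-8.8 -2.99678903
-8.7 -2.99282963
-8.6 -2.98734925
-8.5 -2.98038409
-8.4 -2.97197037
-8.3 -2.96214431
-8.2 -2.95094211
-8.1 -2.9384
-8 -2.92455418
-7.9 -2.90944088
-7.8 -2.8930963
-7.7 -2.87555665
-7.6 -2.85685816
-7.5 -2.83703704
-7.4 -2.81612949
-7.3 -2.79417174
-7.2 -2.7712
-7.1 -2.74725048
-7 -2.7223594
-6.9 -2.69656296
-6.8 -2.66989739
-6.7 -2.6423989
-6.6 -2.6141037
-6.5 -2.58504801
-6.4 -2.55526804
-6.3 -2.5248
-6.2 -2.49368011
-6.1 -2.46194458
-6 -2.42962963
-5.9 -2.39677147
-5.8 -2.36340631
-5.7 -2.32957037
-5.6 -2.29529986
-5.5 -2.260631
-5.4 -2.2256
-5.3 -2.19024307
-5.2 -2.15459643
-5.1 -2.1186963
-5 -2.08257888
-4.9 -2.04628038
-4.8 -2.00983704
-4.7 -1.97328505
-4.6 -1.93666063
-4.5 -1.9
-4.4 -1.86333937
-4.3 -1.82671495
-4.2 -1.79016296
-4.1 -1.75371962
-4 -1.71742112
-3.9 -1.6813037
-3.8 -1.64540357
-3.7 -1.60975693
-3.6 -1.5744
-3.5 -1.539369
-3.4 -1.50470014
-3.3 -1.47042963
-3.2 -1.43659369
-3.1 -1.40322853
-3 -1.37037037
-2.9 -1.33805542
-2.8 -1.30631989
-2.7 -1.2752
-2.6 -1.24473196
-2.5 -1.21495199
-2.4 -1.1858963
-2.3 -1.1576011
-2.2 -1.13010261
-2.1 -1.10343704
-2 -1.0776406
-1.9 -1.05274952
-1.8 -1.0288
-1.7 -1.00582826
-1.6 -0.983870508
-1.5 -0.962962963
-1.4 -0.943141838
-1.3 -0.924443347
-1.2 -0.906903704
-1.1 -0.890559122
-1 -0.875445816
-0.9 -0.8616
-0.8 -0.849057888
-0.7 -0.837855693
-0.6 -0.82802963
-0.5 -0.819615912
-0.4 -0.812650754
-0.3 -0.80717037
-0.2 -0.803210974
-0.1 -0.800808779
0 -0.8
0.1 -0.800808779
0.2 -0.803210974
0.3 -0.80717037
0.4 -0.812650754
0.5 -0.819615912
0.6 -0.82802963
0.7 -0.837855693
0.8 -0.849057888
0.9 -0.8616
1 -0.875445816
1.1 -0.890559122
1.2 -0.906903704
1.3 -0.924443347
1.4 -0.943141838
1.5 -0.962962963
1.6 -0.983870508
1.7 -1.00582826
1.8 -1.0288
1.9 -1.05274952
2 -1.0776406
2.1 -1.10343704
2.2 -1.13010261
2.3 -1.1576011
2.4 -1.1858963
2.5 -1.21495199
2.6 -1.24473196
2.7 -1.2752
2.8 -1.30631989
2.9 -1.33805542
3 -1.37037037
3.1 -1.40322853
3.2 -1.43659369
3.3 -1.47042963
3.4 -1.50470014
3.5 -1.539369
3.6 -1.5744
3.7 -1.60975693
3.8 -1.64540357
3.9 -1.6813037
4 -1.71742112
4.1 -1.75371962
4.2 -1.79016296
4.3 -1.82671495
4.4 -1.86333937
4.5 -1.9
4.6 -1.93666063
4.7 -1.97328505
4.8 -2.00983704
4.9 -2.04628038
5 -2.08257888
5.1 -2.1186963
5.2 -2.15459643
5.3 -2.19024307
5.4 -2.2256
5.5 -2.260631
5.6 -2.29529986
5.7 -2.32957037
5.8 -2.36340631
5.9 -2.39677147
6 -2.42962963
6.1 -2.46194458
6.2 -2.49368011
6.3 -2.5248
6.4 -2.55526804
6.5 -2.58504801
6.6 -2.6141037
6.7 -2.6423989
6.8 -2.66989739
6.9 -2.69656296
7 -2.7223594
7.1 -2.74725048
7.2 -2.7712
7.3 -2.79417174
7.4 -2.81612949
7.5 -2.83703704
7.6 -2.85685816
7.7 -2.87555665
7.8 -2.8930963
7.9 -2.90944088
8 -2.92455418
8.1 -2.9384
8.2 -2.95094211
8.3 -2.96214431
8.4 -2.97197037
8.5 -2.98038409
8.6 -2.98734925
8.7 -2.99282963
8.8 -2.99678903
8.9 -2.99919122
9 -3
9.1 -2.99926337
9.2 -2.99706996
9.3 -2.99344444
9.4 -2.98841152
9.5 -2.98199588
9.6 -2.97422222
9.7 -2.96511523
9.8 -2.95469959
9.9 -2.943
10 -2.93004115
10.1 -2.91584774
10.2 -2.90044444
10.3 -2.88385597
10.4 -2.866107
10.5 -2.84722222
10.6 -2.82722634
10.7 -2.80614403
10.8 -2.784
10.9 -2.76081893
11 -2.73662551
11.1 -2.71144444
11.2 -2.68530041
11.3 -2.65821811
11.4 -2.63022222
11.5 -2.60133745
11.6 -2.57158848
11.7 -2.541
11.8 -2.50959671
11.9 -2.47740329
12 -2.44444444
12.1 -2.41074486
12.2 -2.37632922
12.3 -2.34122222
12.4 -2.30544856
12.5 -2.26903292
12.6 -2.232
12.7 -2.19437449
12.8 -2.15618107
12.9 -2.11744444
13 -2.0781893
13.1 -2.03844033
13.2 -1.99822222
13.3 -1.95755967
13.4 -1.91647737
13.5 -1.875
13.6 -1.83315226
13.7 -1.79095885
13.8 -1.74844444
13.9 -1.70563374
14 -1.66255144
14.1 -1.61922222
14.2 -1.57567078
14.3 -1.53192181
14.4 -1.488
14.5 -1.44393004
14.6 -1.39973663
14.7 -1.35544444
14.8 -1.31107819
14.9 -1.26666255
15 -1.22222222
15.1 -1.17778189
15.2 -1.13336626
15.3 -1.089
15.4 -1.04470782
15.5 -1.0005144
15.6 -0.956444444
15.7 -0.912522634
15.8 -0.868773663
15.9 -0.825222222
16 -0.781893004
16.1 -0.7388107
16.2 -0.696
16.3 -0.653485597
16.4 -0.611292181
16.5 -0.569444444
16.6 -0.527967078
16.7 -0.486884774
16.8 -0.446222222
16.9 -0.406004115
17 -0.366255144
17.1 -0.327
17.2 -0.288263374
17.3 -0.250069959
17.4 -0.212444444
17.5 -0.175411523
17.6 -0.138995885
17.7 -0.103222222
17.8 -0.0681152263
17.9 -0.0336995885
18 0
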