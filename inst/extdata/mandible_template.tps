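LM=15
0.000000 5.000000
1.500000 3.500000
6.000000 4.800000
10.000000 6.000000
16.000000 6.500000
18.500000 9.000000
21.000000 14.000000
22.500000 10.500000
25.000000 12.000000
27.000000 12.500000
26.500000 10.000000
27.500000 5.500000
24.000000 2.500000
14.000000 1.500000
4.000000 2.500000
CURVES=3
POINTS=15
2.812956 2.931578
4.153483 2.453376
5.538415 2.123862
6.953864 1.910614
8.380543 1.765202
9.805933 1.654596
11.230067 1.574330
12.654341 1.523045
14.080153 1.499380
15.508027 1.504408
16.935535 1.547431
18.359626 1.639485
19.777395 1.790800
21.188614 1.996652
22.595412 2.239161
POINTS=15
26.631011 9.737262
26.760748 9.473725
26.887938 9.208588
27.011307 8.941053
27.129582 8.670318
27.241469 8.395598
27.344771 8.116648
27.436047 7.833974
27.511768 7.548137
27.568403 7.259695
27.602424 6.969209
27.612227 6.677181
27.601838 6.383944
27.576305 6.089800
27.540677 5.795051
POINTS=15
18.833555 9.580847
19.167883 10.189226
19.503757 10.852670
19.841951 11.598709
20.183237 12.454877
20.530945 13.373934
20.900251 13.962289
21.301321 13.788767
21.669759 12.975989
21.910445 11.932496
22.085128 11.012875
22.397386 10.520776
23.010269 10.683455
23.741161 11.163084
24.394672 11.599957
ID=template
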