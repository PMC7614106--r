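"day","measurement_mm"
0,2
2,2.316106
4,2.682173
6,3.106098
8,3.597025
10,4.165545
12,4.823921
14,5.586356
16,6.469295
18,7.491786
20,8.675884
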