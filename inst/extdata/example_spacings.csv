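"zone_index","span_um","n_crossings"
0,32.0687129636826,17
0,33.234562884434,17
0,34.4427969831616,17
1,31.4951789471316,15
1,32.5033405757858,15
1,33.5437734886006,15
2,32.3434562233045,14
2,30.8969147144629,13
2,34.2308339381588,14
3,32.7686408263007,13
3,31.052572971055,12
3,34.5354372199393,13
4,30.0310042025765,11
4,33.5622645263197,12
4,31.5175073467647,11
5,32.3220574117373,11
5,33.0775908342134,11
5,33.8507849750406,11
6,31.525747021287,10
6,32.1949680471748,10
6,32.8783951371154,10
7,30.2503459531856,9
7,34.2890801623948,10
7,31.4820720763011,9
8,32.1503659808915,9
8,29.0928495856268,8
8,33.3191843763599,9
9,30.2139122457066,8
9,34.6031044460908,9
9,31.3123313571047,8
10,31.9099229198052,8
10,32.4506832165191,8
10,33.0006074870607,8
11,29.3956461085936,7
11,34.1285717691012,8
11,30.3366016277203,7
12,30.8506996949175,7
12,35.8179002011179,8
12,31.8382315232577,7
13,23.0783530647798,5
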