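species	stage	count
D. melanogaster	input	20590
D. melanogaster	blast1	2251
D. melanogaster	blast2	179
D. melanogaster	phylogeny	0
An. gambiae	input	12659
An. gambiae	blast1	1337
An. gambiae	blast2	154
An. gambiae	phylogeny	0
B. mori	input	14623
B. mori	blast1	1176
B. mori	blast2	163
B. mori	phylogeny	22
T. castaneum	input	9833
T. castaneum	blast1	1493
T. castaneum	blast2	154
T. castaneum	phylogeny	0
Ap. mellifera	input	9257
Ap. mellifera	blast1	1222
Ap. mellifera	blast2	183
Ap. mellifera	phylogeny	79
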