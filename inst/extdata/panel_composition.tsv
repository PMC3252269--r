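level	taxon	organisms	species
total	all	994	680
domain	Eubacteria	926	621
domain	Archaebacteria	68	59
phylum	Proteobacteria	486	315
phylum	Firmicutes	184	99
class	Gammaproteobacteria	236	125
class	Bacilli	133	63
genus	Serratia	NA	1
genus	Photorhabdus	NA	2
genus	Pseudomonas	NA	9
genus	Bacillus	NA	11
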