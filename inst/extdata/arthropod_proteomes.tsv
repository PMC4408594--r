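taxon_id	organism	source	n_proteins	clade
7070	Tribolium castaneum	UniProt	16502	Coleoptera
7159	Aedes aegypti	UniProt	16045	Diptera
7165	Anopheles gambiae	UniProt	13075	Diptera
7176	Culex quinquefasciatus	UniProt	18703	Diptera
7227	Drosophila melanogaster	UniProt	17524	Diptera
7244	Drosophila virilis	UniProt	14457	Diptera
7425	Nasonia vitripennis	HGD	18822	Hymenoptera
13686	Solenopsis invicta	UniProt	14194	Hymenoptera
43151	Anopheles darlingi	UniProt	11437	Diptera
103372	Acromyrmex echinatior	UniProt	13962	Hymenoptera
104421	Camponotus floridanus	UniProt	14787	Hymenoptera
121224	Pediculus humanus corporis	UniProt	10763	Phthiraptera
610380	Harpegnathos saltator	UniProt	15029	Hymenoptera
7460	Apis mellifera	HGD	10570	Hymenoptera
83485	Linepithema humile	HGD	16116	Hymenoptera
12957	Atta cephalotes	HGD	18093	Hymenoptera
144034	Pogonomyrmex barbatus	HGD	17189	Hymenoptera
6669	Daphnia pulex	UniProt	30137	Branchiopoda
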