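species	n_samples	k2p_within
Clarias gariepinus	5	0
Mirogrex terraesanctae	8	0.0019
Luciobarbus longiceps	7	0.0019
Acanthobrama telavivensis	7	0.0019
Capoeta damascina	5	0.0038
Cyprinus carpio	5	0
Garra rufa	14	0.0086
Garra nana	2	0
Carasobarbus canis	11	0.0019
Hypophthalmichthys molitrix	23	0.0057
Pseudophoxinus kervillei	1	0
Oxynoemacheilus leontinae	3	0.0019
Gambusia affinis	3	0
Aphanius mento	1	0
Salaria fluviatilis	8	0.0038
Mugil cephalus	7	0
Chelon ramada	9	0.0019
Astatotilapia flaviijosephi	9	0.0025
Coptodon zillii	8	0
Tristramella simonis	6	0.0019
Sarotherodon galilaeus	21	0
Oreochromis aureus	7	0
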