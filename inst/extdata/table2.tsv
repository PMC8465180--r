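row	wild_species	domestic_species	tissue	n_deg	source_id
1	aggressive foxes (Vulpes vulpes)	tame foxes (V. vulpes)	pituitary	327	B23
2	wolves (Canis familiaris)	dogs (C. lupus)	blood	450	B24
3	wolves (C. lupus)	dogs (C. familiaris)	frontal cortex	13	B25
4	boars (Sus scrofa)	pigs (S. scrofa)	frontal cortex	30	B25
5	cavy (Cavia aperea)	guinea pigs (C. porcellus)	frontal cortex	883	B25
6	wild rabbits (Oryctolagus cuniculus)	domestic rabbits (O. cuniculus domesticus)	frontal cortex	17	B25
7	aggressive rats (R. norvegicus)	tame rats (Rattus norvegicus)	frontal cortex	20	B25
8	boars (S. scrofa)	pigs (S. scrofa)	frontal cortex	34	B26
9	boars (S. scrofa)	pigs (S. scrofa)	pituitary	22	B27
10	wild rabbits (O. cuniculus)	domestic rabbits (O. cuniculus domesticus)	parietal-temporal cortex	216	B28
11	wild rabbits (O. cuniculus)	domestic rabbits (O. cuniculus domesticus)	amygdala	118	B28
12	wild rabbits (O. cuniculus)	domestic rabbits (O. cuniculus domesticus)	hypothalamus	43	B28
13	wild rabbits (O. cuniculus)	domestic rabbits (O. cuniculus domesticus)	hippocampus	100	B28
14	wild chicken (G. gallus)	domestic chicken (Gallus gallus)	pituitary	474	B29
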