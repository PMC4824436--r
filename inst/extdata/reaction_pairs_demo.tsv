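# Curated demonstration set of enzymatic reactant pairs touching the cohort
# metabolites: methionine salvage / sulfur amino acid metabolism, TCA cycle,
# glycine-serine interconversion, polyamine synthesis. One pair per line,
# tab-separated. Pairs with an endpoint outside the cohort are dropped at
# load time.
Methionine	Methionine sulfoxide
Methionine	5'-Deoxy-5'-methylthioadenosine
Methionine	S-Adenosylmethionine
Serine	Glycine
Fumaric acid	Malate
Ornithine	Putrescine
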