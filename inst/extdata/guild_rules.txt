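# Lineage keywords for guild assignment by phylogenetic affiliation.
# Case-insensitive substring match against the full lineage string,
# so family- and genus-level names both work.

[syntrophs]
Syntrophomonas
Syntrophobacter
Syntrophorhabdus
Syntrophaceae
Syntrophus
Smithella
Pelotomaculum

[methanogens]
Methanosaeta
Methanothrix
Methanosarcina
Methanobacterium
Methanobrevibacter
Methanomassiliicoccus
Methanofastidiosum
Methanospirillum
Methanoculleus
Methanolinea
Methanoregula
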