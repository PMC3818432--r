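# synthetic IRES group template (generated stand-in, not a database entry)
group: 4
name: PV
accession: V01148.1
cutoff_r: 1.58
sequence: ACUGCCCGCACGGGGAUGCCUGUGCGGGCAUCGUGGGCUCUGAUGUUCACUCCCUAGGGAGUGAACCACGAGAUGUGGUGGCAUAUCUCGUCCAGGGCCCACCUGUUCGCUCUUCCUAGGGAGCGAACCUGGUGAACCCAGAGGUUCACCGC
structure: ..((((((((((((....))))))))))))..((((((((((..(((((((((....)))))))))..(((((((((....)))))))))..))))))))))..((((((((((....))))))))))..((((((((....))))))))..
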