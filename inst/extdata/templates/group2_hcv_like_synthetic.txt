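# synthetic IRES group template (generated stand-in, not a database entry)
group: 2
name: HCV
accession: AF177037
cutoff_r: 1.98
sequence: GAUUGCGAUGGGUGGGUUCAGCUAUCGUCAGUAUGAUGGCUGUAGGAGCUCGCAUAGCGUGCGGCUACGCACGCUGCUGUGGGUCUAUGGACCCACAAUGCGGGUUCCUCGGCCCUCCGCAUGAGCGGAGGGCCGGACGGGACAGACGUGUCCCGUGCCCCACUCAUCGCAAGCGCGUCCGUGAUGCCACGGACGCAU
structure: ..((((((((((((((..((((((((((....))))))))))..(((((((((..((((((((....))))))))..((((((((....))))))))..)))))))))..((((((((((....))))))))))..((((((((....))))))))..))))))))))))))..(((((((((....)))))))))..
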