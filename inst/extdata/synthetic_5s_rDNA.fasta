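>synthetic_5S_rDNA synthetic canonical 5S rDNA-like internal control region (box A / IE / box C); not a natural sequence
GCCTACGGCCATACCACCCTGAAAGCACCGGGGTCGGGCCTGGTTAGTACTTGGATGGAT
ACCAGGGAGACCGCCTGGTGCTGTAGGCTTATGCAGGATCCACCGAAT
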