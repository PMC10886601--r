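# 5S rRNA (RNA polymerase III type 1) internal control region motifs.
# IUPAC strings; spacings are nt between the end of one motif and the start
# of the next, written lo-hi. These defaults were derived from the synthetic
# canonical internal-control-region sequence shipped alongside
# (synthetic_5s_rDNA.fasta) and can be replaced by a user configuration.
boxA = GGGTCGGGCCTGG
ie = CTTGGATGG
boxC = GAGACCGCCTGG
gap_a_ie = 2-10
gap_ie_c = 5-15
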