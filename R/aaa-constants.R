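# allele codes and the fixed state order used throughout
ALLELES <- c("M", "P")
STATES <- c("P", "B", "M")
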