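# gene order used by the simulator backend and all state layouts
GENE_ORDER <- c("GAL1", "GAL3", "GAL80", "REPORTER")
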