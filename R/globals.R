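# data.table NSE column names used inside [] expressions.
utils::globalVariables(c("gene_name", "biotype", ".N", "overall_fraction",
                         "transcript_count", "overall_rank", "mean_fraction"))
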