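category	n_concordant	n_total
variants	69	85
amplifications	21	23
homozygous_deletions	8	15
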