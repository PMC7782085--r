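n_actionable	n_validated	n_actionable_concordant
70	123	53
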