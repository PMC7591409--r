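status,n_baseline,no_falls,one_fall,recurrent
non_frail,799,547,84,62
frail,245,107,42,72
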