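group,n_start,n_pupae,n_adult_female,n_adult_male
CG,30,14,8,6
ST,90,13,7,6
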