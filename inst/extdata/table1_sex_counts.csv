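group,female,male
Canada,18,36
Australia_I,37,51
Australia_II,17,39
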