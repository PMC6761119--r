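gene_id
ABCA1
ALDH4A1
FZD4
GPAM
GPD1
LPIN1
MMD
PPARG
PPIF
SCAMP3
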