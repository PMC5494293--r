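hsa-miR-324-5p
hsa-miR-29c-5p
hsa-miR-107
hsa-miR-324-3p
hsa-miR-30d-5p
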