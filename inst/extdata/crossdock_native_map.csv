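ligand_id,native_conformation
3B66,3B66
3G0W,3G0W
3V49,3V49
4HLW,4HLW
2PNU,2PNU
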