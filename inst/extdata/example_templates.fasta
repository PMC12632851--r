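>eco3_like synthetic Eco3-like template loop with flanks
GGCGCAAUGAUUCCAAUCACG
>telomeric_design synthetic chimera encoding the human telomeric repeat TTAGGG
GGCGCCCUAACCCCACG
>no_pattern synthetic loop too short to host a pattern
GGCGACGUCACG
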