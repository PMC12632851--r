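id	loop_start	loop_end	dot_bracket
eco3_like	5	17	NA
telomeric_design	5	13	NA
no_pattern	5	8	NA
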