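"taxon","status"
"t001","nonnodulating"
"t002","nonnodulating"
"t003","nonnodulating"
"t004","nonnodulating"
"t005","unknown"
"t006","FT"
"t007","nonnodulating"
"t008","nonnodulating"
"t009","FT"
"t010","SYM"
"t011","SYM"
"t012","nonnodulating"
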