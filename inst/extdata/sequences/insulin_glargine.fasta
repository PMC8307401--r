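>insulin_glargine_A A chain (A21 Gly)
GIVEQCCTSICSLYQLENYCG
>insulin_glargine_B B chain (B31-B32 Arg-Arg)
FVNQHLCGSHLVEALYLVCGERGFFYTPKTRR
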