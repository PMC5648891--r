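>ST1
AAAACTCC
>ST2
ATGTGTAA
>ST3
GTAGAATC
>ST4
GGCCTTTC
>ST5
CATATCTC
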