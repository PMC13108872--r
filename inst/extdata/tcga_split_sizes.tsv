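partition	size
train	8305
val	443
test	1350
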