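class	count
C	3612988
M	2529
N	969253
O	1088410
S	28502
X	4299
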