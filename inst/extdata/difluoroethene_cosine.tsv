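	cis-1,2-difluoro	trans-1,2-difluoro	1,1-difluoro
cis-1,2-difluoro	0	0.04200	0.09497
trans-1,2-difluoro	0.04200	0	0.10219
1,1-difluoro	0.09497	0.10219	0
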