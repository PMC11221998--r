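chrY	2654895	2655782	SRY
chrY	2709526	2734994	RPS4Y1
chrY	2803517	2850547	ZFY
chrY	14813159	14972768	USP9Y
chrY	15016018	15032390	DDX3Y
chrY	15360258	15592553	UTY
chrY	22737610	22755040	EIF1AY
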