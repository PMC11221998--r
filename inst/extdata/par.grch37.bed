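chrX	60000	2699520	PAR1_X
chrY	10000	2649520	PAR1_Y
chrX	154931043	155260560	PAR2_X
chrY	59034049	59363566	PAR2_Y
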