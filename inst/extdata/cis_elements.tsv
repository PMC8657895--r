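name	consensus	note
ABRE	ACGTG	abscisic acid responsiveness (ABA-responsive element core)
CGTCA-motif	CGTCA	MeJA responsiveness (jasmonate)
GARE-motif	TCTGTTG	gibberellin-responsive element
LTR	CCGAAA	low-temperature responsiveness
MBS	CAACTG	MYB binding site involved in drought inducibility
MRE	AACCTAA	MYB binding site involved in light responsiveness
MYB	CAACAG	MYB transcription-factor binding site
P-box	CCTTTTG	gibberellin-responsive element (pyrimidine box)
TCA-element	CCATCTTTTT	salicylic acid responsiveness
TCT-motif	TCTTAC	part of a light-responsive element
TGACG-motif	TGACG	MeJA responsiveness (jasmonate)
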