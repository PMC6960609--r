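db,negative,positive,surprise
CASME1,52,9,20
CASME2,88,32,25
CASME_SQ2,28,16,10
SMIC_HS,70,51,43
SAMM,91,26,15
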