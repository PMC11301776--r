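>ALB_HUMAN_MINI synthetic mini-protein embedding ALB quantotypic peptides
LVNEVTEFAKQTALVELVK
>DBP_HUMAN_MINI synthetic mini-protein embedding DBP quantotypic peptides
TSALSAKVLEPTLK
>SERPING1_HUMAN_MINI synthetic mini-protein embedding SERPING1 quantotypic peptide
FQPTLLTLPR
>ANXA1_HUMAN_MINI synthetic mini-protein embedding ANXA1 quantotypic peptide
GVDEATIIDILTK
>PRKDC_HUMAN_MINI synthetic mini-protein embedding PRKDC quantotypic peptide
DQNILLGTTYR
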