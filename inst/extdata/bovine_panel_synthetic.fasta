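>ALB_BOVIN_MINI synthetic mini-protein embedding ALB surrogate peptides
LVNELTEFAKQTALVELLK
>DBP_BOVIN_MINI synthetic mini-protein embedding DBP surrogate peptides
TSALSDKILESTLK
>SERPING1_BOVIN_MINI synthetic mini-protein embedding SERPING1 surrogate peptide
FHPTHLTMPR
>ANXA1_BOVIN_MINI synthetic mini-protein embedding ANXA1 surrogate peptide
GVDEATIIEILTK
>PRKDC_BOVIN_MINI synthetic mini-protein embedding PRKDC surrogate peptide
DHHVLLGTTYR
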