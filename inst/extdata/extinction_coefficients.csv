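wavelength_nm,eps_hbo2_cm1_mM1,eps_hbr_cm1_mM1
770,0.6500,1.3622
850,1.0580,0.6913
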