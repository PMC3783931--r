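# strokemismatch pipeline configuration (flat key = value; see
# default_config() for the full parameter list and units)
dwi_k = 2
adc_max = 620e-6
ttp_delay_threshold = 4
volume_threshold_mL = 10
ratio_threshold = 1.2
ratio_convention = pwi_over_dwi
window_h = 4.5
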