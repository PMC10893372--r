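{
  "comment": "Synthetic placeholder compositions for demonstration and testing. The reference ratios follow representative natural Cd isotope abundances (110:111:113:114 ~ 12.49:12.80:12.22:28.73) and the spike is a notional ~equal 111Cd-113Cd double spike; neither is a certified composition of NIST SRM-3108 or of any real spike batch. Edit before use with real data.",
  "isotope_masses": [109.9030021, 110.9041781, 112.9044017, 113.9033585],
  "reference_ratios": [1.024820, 0.978383, 2.300240],
  "spike_ratios": [48.0, 46.0, 3.0],
  "spike_conc_ng_g": 100.0
}
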