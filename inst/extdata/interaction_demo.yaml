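loci:
- name: risk_variant
  allele_labels:
  - carrier
  - noncarrier
  risk_allele_freq: 0.5
  sampling_mode: binomial
strata:
- name: hsv_negative
  size: 700
  exposures:
    infection: 0.0
- name: hsv_positive
  size: 300
  exposures:
    infection: 1.0
penetrance:
  locus: risk_variant
  background_mortality: 0.0
  entries:
  - genotype: carrier
    stratum: hsv_negative
    infection: 0.0
    death_prob: 0.1764705882352941
  - genotype: noncarrier
    stratum: hsv_negative
    infection: 0.0
    death_prob: 0.29999999999999999
  - genotype: carrier
    stratum: hsv_positive
    infection: 1.0
    death_prob: 0.4705882352941177
  - genotype: noncarrier
    stratum: hsv_positive
    infection: 1.0
    death_prob: 0.10000000000000001
n_null_loci: 0
null_locus_freq: 0.5
seed: 1
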