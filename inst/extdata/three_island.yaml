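loci:
- name: colour
  allele_labels:
  - black
  - white
  risk_allele_freq: 0.5
  sampling_mode: exact_count
strata:
- name: snow_island
  size: 1000
  exposures:
    fox: 1.0
- name: ash_island
  size: 1000
  exposures:
    fox: 1.0
- name: no_fox_island
  size: 1000
  exposures:
    fox: 0.0
penetrance:
  locus: colour
  background_mortality: 0.0
  entries:
  - genotype: black
    stratum: snow_island
    fox: 1.0
    death_prob: 1.0
  - genotype: white
    stratum: snow_island
    fox: 1.0
    death_prob: 0.0
  - genotype: white
    stratum: ash_island
    fox: 1.0
    death_prob: 1.0
  - genotype: black
    stratum: ash_island
    fox: 1.0
    death_prob: 0.0
  - genotype: black
    stratum: no_fox_island
    fox: 0.0
    death_prob: 0.10000000000000001
  - genotype: white
    stratum: no_fox_island
    fox: 0.0
    death_prob: 0.10000000000000001
n_null_loci: 0
null_locus_freq: 0.5
seed: 1
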