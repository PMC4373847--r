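# Tonatia saurophila: 2n = 16, FN = 20; three bi-armed and four one-armed
# autosome pairs. Individual pair morphologies beyond the bi-/one-armed split
# are not enumerated, so bi-armed pairs are listed first by convention.
species_code: TSA
diploid_number: 16
fundamental_number: 20
autosome_pairs:
  - {label: TSA-1, morphology: bi_armed}
  - {label: TSA-2, morphology: bi_armed}
  - {label: TSA-3, morphology: bi_armed}
  - {label: TSA-4, morphology: one_armed}
  - {label: TSA-5, morphology: one_armed}
  - {label: TSA-6, morphology: one_armed}
  - {label: TSA-7, morphology: one_armed}
sex_system:
  - {label: TSA-X, morphology: submetacentric}
  - {label: TSA-Y, morphology: acrocentric}
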