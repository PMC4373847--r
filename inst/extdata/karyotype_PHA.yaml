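# Phyllostomus hastatus, the reference complement (minimal conserved units):
# 2n = 32, FN = 58; pair 15 is acrocentric (distal NOR), all other autosomes
# bi-armed.
species_code: PHA
diploid_number: 32
fundamental_number: 58
autosome_pairs:
  - {label: PHA-1, morphology: bi_armed}
  - {label: PHA-2, morphology: bi_armed}
  - {label: PHA-3, morphology: bi_armed}
  - {label: PHA-4, morphology: bi_armed}
  - {label: PHA-5, morphology: bi_armed}
  - {label: PHA-6, morphology: bi_armed}
  - {label: PHA-7, morphology: bi_armed}
  - {label: PHA-8, morphology: bi_armed}
  - {label: PHA-9, morphology: bi_armed}
  - {label: PHA-10, morphology: bi_armed}
  - {label: PHA-11, morphology: bi_armed}
  - {label: PHA-12, morphology: bi_armed}
  - {label: PHA-13, morphology: bi_armed}
  - {label: PHA-14, morphology: bi_armed}
  - {label: PHA-15, morphology: acrocentric}
sex_system:
  - {label: PHA-X, morphology: submetacentric}
  - {label: PHA-Y, morphology: acrocentric}
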