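# Phyllostomus discolor: 2n = 32, FN = 60; all chromosomes bi-armed except the
# acrocentric Y. Pair 15 is metacentric (pericentric inversion relative to the
# acrocentric pair 15 of PHA and LSI), with a distal NOR.
species_code: PDI
diploid_number: 32
fundamental_number: 60
autosome_pairs:
  - {label: PDI-1, morphology: bi_armed}
  - {label: PDI-2, morphology: bi_armed}
  - {label: PDI-3, morphology: bi_armed}
  - {label: PDI-4, morphology: bi_armed}
  - {label: PDI-5, morphology: bi_armed}
  - {label: PDI-6, morphology: bi_armed}
  - {label: PDI-7, morphology: bi_armed}
  - {label: PDI-8, morphology: bi_armed}
  - {label: PDI-9, morphology: bi_armed}
  - {label: PDI-10, morphology: bi_armed}
  - {label: PDI-11, morphology: bi_armed}
  - {label: PDI-12, morphology: bi_armed}
  - {label: PDI-13, morphology: bi_armed}
  - {label: PDI-14, morphology: bi_armed}
  - {label: PDI-15, morphology: metacentric}
sex_system:
  - {label: PDI-X, morphology: bi_armed}
  - {label: PDI-Y, morphology: acrocentric}
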