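# Lophostoma silvicola: 2n = 34, FN = 60; 28 bi-armed and 4 one-armed
# autosomes. The acrocentrics are pairs 15 (heterochromatic long arm, distal
# NOR) and 16; the X is metacentric and the Y acrocentric.
species_code: LSI
diploid_number: 34
fundamental_number: 60
autosome_pairs:
  - {label: LSI-1, morphology: bi_armed}
  - {label: LSI-2, morphology: bi_armed}
  - {label: LSI-3, morphology: bi_armed}
  - {label: LSI-4, morphology: bi_armed}
  - {label: LSI-5, morphology: bi_armed}
  - {label: LSI-6, morphology: bi_armed}
  - {label: LSI-7, morphology: bi_armed}
  - {label: LSI-8, morphology: bi_armed}
  - {label: LSI-9, morphology: bi_armed}
  - {label: LSI-10, morphology: bi_armed}
  - {label: LSI-11, morphology: bi_armed}
  - {label: LSI-12, morphology: bi_armed}
  - {label: LSI-13, morphology: bi_armed}
  - {label: LSI-14, morphology: bi_armed}
  - {label: LSI-15, morphology: acrocentric}
  - {label: LSI-16, morphology: acrocentric}
sex_system:
  - {label: LSI-X, morphology: metacentric}
  - {label: LSI-Y, morphology: acrocentric}
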