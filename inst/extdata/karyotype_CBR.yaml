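# Carollia brevicauda, second probe panel: 2n = 20 (female) / 21 (male),
# FN = 36, with an XY1Y2 multiple sex-chromosome system. The male complement
# is listed so that the Y2 probe label validates.
species_code: CBR
diploid_number: 21
fundamental_number: 36
autosome_pairs:
  - {label: CBR-1, morphology: bi_armed}
  - {label: CBR-2, morphology: bi_armed}
  - {label: CBR-3, morphology: bi_armed}
  - {label: CBR-4, morphology: bi_armed}
  - {label: CBR-5, morphology: bi_armed}
  - {label: CBR-6, morphology: bi_armed}
  - {label: CBR-7, morphology: bi_armed}
  - {label: CBR-8, morphology: bi_armed}
  - {label: CBR-9, morphology: bi_armed}
sex_system:
  - {label: CBR-X, morphology: bi_armed}
  - {label: CBR-Y1, morphology: one_armed}
  - {label: CBR-Y2, morphology: one_armed}
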