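# probe_species: PHA
# target_species: PDI
# note: only PHA-14 and PHA-15 were hybridized, the PDI karyotype being otherwise conserved relative to PHA; both probes paint whole PDI chromosomes despite the metacentric form of PDI-15.
probe	target	n_blocks	region
PHA-14	PDI-14	1
PHA-15	PDI-15	1
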