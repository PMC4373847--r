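# probe_species: CBR
# target_species: TSA
# note: CBR-4 gives three signals on two chromosomes (TSA-3 and TSA-7) and CBR-2 five signals on four chromosomes; the chromosome carrying the doubled block is not identified, so it is assigned to the first-listed target.
# Whole-chromosome CBR probes on Tonatia saurophila metaphases; 31 homologous
# segments in total. CBR-1 shows two blocks on TSA-6, matching PHA-5.
probe	target	n_blocks	region
CBR-7	TSA-5	1
CBR-9	TSA-6	1
CBR-X	TSA-X	1
CBR-8	TSA-1	1
CBR-8	TSA-5	1
CBR-5	TSA-4	1
CBR-5	TSA-7	1
CBR-4	TSA-3	2
CBR-4	TSA-7	1
CBR-6	TSA-1	1
CBR-6	TSA-2	1
CBR-6	TSA-5	1
CBR-3	TSA-2	1
CBR-3	TSA-3	1
CBR-3	TSA-4	1
CBR-3	TSA-7	1
CBR-2	TSA-1	2
CBR-2	TSA-2	1
CBR-2	TSA-4	1
CBR-2	TSA-5	1
CBR-1	TSA-1	1
CBR-1	TSA-2	1
CBR-1	TSA-4	1
CBR-1	TSA-6	2
CBR-Y2	TSA-1	1
CBR-Y2	TSA-2	1
CBR-Y2	TSA-3	1
CBR-Y2	TSA-5	1
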