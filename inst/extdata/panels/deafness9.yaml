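# Nine-locus hereditary hearing-loss 2D-PCR panel.
# Each allele occupies one point in (fluorophore channel, Tm) space; the
# tag is the lowercase 5' extension of the allele-specific forward primer,
# homologous (with deliberate mismatches) to the channel probe.
name: deafness9
tolerance_c: 1.0

loci:
  - gene: SLC26A4
    locus_id: "c.919-2A>G"
    ploidy: diploid
  - gene: GJB2
    locus_id: "c.235delC"
    ploidy: diploid
  - gene: GJB2
    locus_id: "c.176-191del16"
    ploidy: diploid
  - gene: GJB2
    locus_id: "c.299_300delAT"
    ploidy: diploid
  - gene: SLC26A4
    locus_id: "c.1229C>T"
    ploidy: diploid
  - gene: SLC26A4
    locus_id: "c.2168A>G"
    ploidy: diploid
  - gene: GJB3
    locus_id: "c.538C>T"
    ploidy: diploid
  - gene: MT-RNR1
    locus_id: "m.1494C>T"
    ploidy: mitochondrial
  - gene: MT-RNR1
    locus_id: "m.1555A>G"
    ploidy: mitochondrial

probes:
  - channel: FAM
    label: FAM
    sequence: ccatctacactcccaaactaatcttttcttccttatctc
  - channel: HEX
    label: HEX
    sequence: cctaatcatcaaccacttaccatcacttcacctatccat
  - channel: Alexa568
    label: Alexa568
    sequence: cacctatccttctatcattcctttccattcaatactcct

coordinates:
  - {locus_id: "c.919-2A>G",     allele: wild,   channel: FAM,      tm_c: 66.8}
  - {locus_id: "c.919-2A>G",     allele: mutant, channel: HEX,      tm_c: 67.2}
  - {locus_id: "c.235delC",      allele: wild,   channel: FAM,      tm_c: 64.4}
  - {locus_id: "c.235delC",      allele: mutant, channel: HEX,      tm_c: 63.2}
  - {locus_id: "c.176-191del16", allele: wild,   channel: FAM,      tm_c: 59.6}
  - {locus_id: "c.176-191del16", allele: mutant, channel: HEX,      tm_c: 59.6}
  - {locus_id: "c.299_300delAT", allele: wild,   channel: FAM,      tm_c: 53.2}
  - {locus_id: "c.299_300delAT", allele: mutant, channel: HEX,      tm_c: 56.4}
  - {locus_id: "c.1229C>T",      allele: wild,   channel: FAM,      tm_c: 48.4}
  - {locus_id: "c.1229C>T",      allele: mutant, channel: Alexa568, tm_c: 66.0}
  - {locus_id: "c.2168A>G",      allele: wild,   channel: FAM,      tm_c: 41.2}
  - {locus_id: "c.2168A>G",      allele: mutant, channel: Alexa568, tm_c: 62.0}
  - {locus_id: "c.538C>T",       allele: wild,   channel: FAM,      tm_c: 36.4}
  - {locus_id: "c.538C>T",       allele: mutant, channel: Alexa568, tm_c: 50.4}
  - {locus_id: "m.1494C>T",      allele: wild,   channel: HEX,      tm_c: 47.2}
  - {locus_id: "m.1494C>T",      allele: mutant, channel: Alexa568, tm_c: 41.6}
  - {locus_id: "m.1555A>G",      allele: wild,   channel: HEX,      tm_c: 42.4}
  - {locus_id: "m.1555A>G",      allele: mutant, channel: Alexa568, tm_c: 35.6}

# Allele-specific forward primers are tag (lowercase) + specific 3' region
# (uppercase).  artificial_mismatch_pos counts from the 3' end (the
# 3'-terminal, allele-discriminating base is position 1); null when the
# primer carries no engineered destabilising mismatch.
oligos:
  - locus_id: "c.919-2A>G"
    allele: wild
    channel: FAM
    tag: ccatctacactcccaaactgatcttttcttccttatctc
    specific_primer: AAATGGCAGTAGCAATTATCGCCT
    artificial_mismatch_pos: 3
    reverse_primer: CCAATGGAGTTTTTAACATCTTTTG
  - locus_id: "c.235delC"
    allele: wild
    channel: FAM
    tag: ccatctacactcccaaacgcttcttttcttccttatctc
    specific_primer: ACACGAAGATCAGCTGCACGG
    artificial_mismatch_pos: 3
    reverse_primer: CATCTCCCACATCCGGCTAT
  - locus_id: "c.176-191del16"
    allele: wild
    channel: FAM
    tag: ccatctacactcccaaagctgcattttcttccttatctc
    specific_primer: GGAAGTAGTGATCGTAGCACACGTT
    artificial_mismatch_pos: null
    reverse_primer: CGACTTTGTCTGCAACACCCT
  - locus_id: "c.299_300delAT"
    allele: wild
    channel: FAM
    tag: ccatctacactcccagtgaggatgattcttccttatctc
    specific_primer: CCTTGATGAACTTCCTCTTCTTATCATG
    artificial_mismatch_pos: 6
    reverse_primer: CAGCGCTCCTAGTGGCCAT
  - locus_id: "c.1229C>T"
    allele: wild
    channel: FAM
    tag: ccatctacactcctgtgagctaagacgcttccttatctc
    specific_primer: AGTGCTCTCCTGGACGGACG
    artificial_mismatch_pos: 3
    reverse_primer: GGATTCTTCTCTTGTTTTGTGGC
  - locus_id: "c.2168A>G"
    allele: wild
    channel: FAM
    tag: ccatcttaggatccaaactaatcttttacggacaatctc
    specific_primer: AGGACACATTCTTTTTGACGGTACA
    artificial_mismatch_pos: 3
    reverse_primer: CTCTTGAGATTTCACTTGGTTCTGT
  - locus_id: "c.538C>T"
    allele: wild
    channel: FAM
    tag: ccatcttgcactagaaactaatctttatgcgaacatctc
    specific_primer: ATCGTGGACTGCTACATGGCCC
    artificial_mismatch_pos: 5
    reverse_primer: GCCCACCATGAAGTAGGTGAAG
  - locus_id: "c.919-2A>G"
    allele: mutant
    channel: HEX
    tag: cctaatcatcaaccacacgccatcacttcacctatccat
    specific_primer: TGAAATGGCAGTAGCAATTATAGTCC
    artificial_mismatch_pos: 5
    reverse_primer: CCAATGGAGTTTTTAACATCTTTTG
  - locus_id: "c.235delC"
    allele: mutant
    channel: HEX
    tag: cctaatcatcaaccacgacagatcacttcacctatccat
    specific_primer: GACACGAAGATCAGCTGAAGGC
    artificial_mismatch_pos: 5
    reverse_primer: CATCTCCCACATCCGGCTAT
  - locus_id: "c.176-191del16"
    allele: mutant
    channel: HEX
    tag: cctaatcatcaaccaccagatcgtacttcacctatccat
    specific_primer: GGGGAAGTAGTGATCGTACCTGG
    artificial_mismatch_pos: 5
    reverse_primer: CGACTTTGTCTGCAACACCCT
  - locus_id: "c.299_300delAT"
    allele: mutant
    channel: HEX
    tag: cctaatcatcaaccacaattttaagattcacctatccat
    specific_primer: CCTTGATGAACTTCCTCTTCTACTCG
    artificial_mismatch_pos: 5
    reverse_primer: CAGCGCTCCTAGTGGCCAT
  - locus_id: "m.1494C>T"
    allele: wild
    channel: HEX
    tag: cctaatcatcgttcacttaccatatagctcgacgtccat
    specific_primer: AATGTCCTTTGAAGTATACTTGAGCAGG
    artificial_mismatch_pos: 4
    reverse_primer: TGAAGCGCGTACACACCG
  - locus_id: "m.1555A>G"
    allele: wild
    channel: HEX
    tag: cctaatcatcacgtacttaccgcgcgaagttaattccat
    specific_primer: CCAGTACACTTACCATGTTACGAATTGT
    artificial_mismatch_pos: 5
    reverse_primer: ACTAAAACCCCTACGCATTTATATAGAG
  - locus_id: "c.1229C>T"
    allele: mutant
    channel: Alexa568
    tag: cacctatccttctatcatttctttccattcaatactcct
    specific_primer: AGTGCTCTCCTGGAAGGCCA
    artificial_mismatch_pos: 6
    reverse_primer: GGATTCTTCTCTTGTTTTGTGGC
  - locus_id: "c.2168A>G"
    allele: mutant
    channel: Alexa568
    tag: cacctatccttctatcattgatttccattcaatactcct
    specific_primer: GACACATTCTTTTTGACGGGCCG
    artificial_mismatch_pos: 4
    reverse_primer: CTCTTGAGATTTCACTTGGTTCTGT
  - locus_id: "m.1494C>T"
    allele: mutant
    channel: Alexa568
    tag: cacctatccttctaaatccaaaccatattcaatactcct
    specific_primer: AAATGTCCTTTGAAGTATACTTGACGAGA
    artificial_mismatch_pos: 5
    reverse_primer: TGAAGCGCGTACACACCG
  - locus_id: "m.1555A>G"
    allele: mutant
    channel: Alexa568
    tag: cacctatccaggtatcattcctttgatcgagtcgctcct
    specific_primer: CAGTACACTTACCATGTTACGACGTGC
    artificial_mismatch_pos: 4
    reverse_primer: ACTAAAACCCCTACGCATTTATATAGAG
  - locus_id: "c.538C>T"
    allele: mutant
    channel: Alexa568
    tag: cacctatatgcatatcattcctggtgtgctcatactcct
    specific_primer: CATCGTGGACTGCTACATTCCCT
    artificial_mismatch_pos: 4
    reverse_primer: GCCCACCATGAAGTAGGTGAAG
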