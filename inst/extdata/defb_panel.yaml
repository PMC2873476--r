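# Beta-defensin (DEFB) amplicon panel: six amplicons (F2, F4-F8) spanning
# 26 MSVs of the copy-number variable cluster at chromosome 8p23.1.
# MSV structure (amplicon membership, counts, allele sets, forward/reverse
# read coverage of F5) follows the published haplotype tables.
# Reference sequences and MSV offsets are SYNTHETIC (deterministically
# generated stand-ins; the original primer/position tables are not
# redistributed here). Genomic positions (hg18, 1-based) are given only for
# the two MSVs whose coordinates are published: MSV9a (a paralogous
# sequence variation present in the reference assembly) and MSV10a (novel).
amplicons:
  F2:
    reference: >-
      CAGTGTGTCATGTCTTCAAACGTCATCCGCAGGCGAGTCAGGTCTGTATGCCTGTCGTAT
      GCATTCCCTTGTCCTCAGGGTGTCCCCCCTGTTCATATGAACCAGGGTCATAGCTGCCGC
      ACTTGTGGTCAGATAGCTGTATAAGTTGTTTTAAGAAAATGCACGGTATTCATCCTCTTG
      AAGCCAGTGCTGCTCATGCAGGAACAGGCACGACAGACCGGAATAC
    msvs: [MSV1, MSV2]
  F4:
    reference: >-
      CGACAGTCCGTAACCAGGTATCTCATTCGCTTTCGCAGGTCGCCTGGATGAGGAGTGTCA
      TGCCGACCGAGGAGGCAAGACTGGTTTGTATCCCACGATATTTAAGTGAGAGAGACCGCG
      CTGAAGGGTCACATTGTTGGTTTCTCTCTGAACTAGATCTGAACAATCCGCGCGTCTCGT
      ACCTGGCAGGTGCCTAGTATATATAAAGGTATGAAACCGCCCAGATTCATGAGCAACACT
      TACGGAGG
    msvs: [MSV3, MSV4, MSV5]
  F5:
    reference: >-
      CGAAGAATTTCTTTATCATTCTTAGACGCCGCAACATATATATCTTAGCAGAACGTTAAG
      GTGCAATCATACACATCCTCTCTGTTTAAGATTCTCGAACTGCGGGGAGCTATCAGTTAG
      CAATGGCATACACTCGGCTGGGGAGGATGGCGGCGAGACCGTGTACAGAGGAGTGCCTCG
      TTTATCAGACCGGGAGATGTGGGAAACTACACCCCTGTGCTGTATCTGAGCGCCTTTGGT
      GCAGTTGAGACCTCATACGATTGTTTCCGGGGTGCGTATGCGGGTTCGACTGTTGACATG
      AAAACCATTGTTGGAAAAAGCCTGGGAGTATTTCGTGTTG
    msvs: [MSV6, MSV7, MSV8, MSV9, MSV9a, MSV10, MSV10a]
    forward_set: [MSV6, MSV7, MSV8]
    reverse_set: [MSV7, MSV8, MSV9, MSV9a, MSV10, MSV10a]
  F6:
    reference: >-
      TTCTCCTAAGTCGTCAAGTCGAGGAGATATTTGTAGACGATGTATATCTACGATTAAATG
      CGGCGGTATATCCTTTACATATGTGCGTATCGTCGATCCGGCCTCGATGCCTAGGAGCGG
      TAGGCTCGAAGTATCTGAAAAAGCGACACTTTGTTCTGTGGCGCGGTCCTAGCGCCCCTT
      GTTCGTACGAGATGAAGTTACAGGCAATCTCGCTGATTTCTTACGGAGGCAC
    msvs: [MSV11, MSV12, MSV13, MSV14, MSV15]
  F7:
    reference: >-
      GGAAGGTTATAAATGTAAAGGCCGGGAATTGCCAACATCTGTAGATGTTTGTGACTGACT
      GTGCTTGTAGGCTACGCTCCTAGCGCTCTGTATGGGCCAATAAGCCCCTGCATATTGGTC
      CCTTTTTGGTATAGCAGAGTTAAGGGAGCGCGGCTTGTTGGTCTCGCAAGCAACGGGTAT
      TTTCATAACTTTTAAACACGACTCGGCGAGTC
    msvs: [MSV16, MSV17, MSV18]
  F8:
    reference: >-
      CTATTAATGGGGGATATATCTACTCACCACACAGTCCGGGTTTAACGGTGGTTAATGAGC
      TACACGGAGCTACAATGGGTAGAAAGGAGTGCCAAGAAATCACTTGGCGCAGATTACGGA
      ATTCCCCGGCCCTACACGTACGTACACAAGAAACGTTTGCCATGCAGACTTGCGGCATGT
      GTTCGAAGTATTGGTCGATGGGGCCCGTGCGCACCTCGTACGCGTGCTGATTCATTTCCA
    msvs: [MSV19, MSV20, MSV21, MSV22, MSV23, MSV24]
msvs:
  MSV1:  {amplicon: F2, offset: 70,  alleles: [G, C], novelty: known}
  MSV2:  {amplicon: F2, offset: 120, alleles: [A, G], novelty: known}
  MSV3:  {amplicon: F4, offset: 60,  alleles: [T, C], novelty: known}
  MSV4:  {amplicon: F4, offset: 110, alleles: [A, C], novelty: known}
  MSV5:  {amplicon: F4, offset: 170, alleles: [C, T], novelty: known}
  MSV6:  {amplicon: F5, offset: 40,  alleles: [T, C], novelty: known}
  MSV7:  {amplicon: F5, offset: 150, alleles: [C, T], novelty: known}
  MSV8:  {amplicon: F5, offset: 185, alleles: [C, G], novelty: known}
  MSV9:  {amplicon: F5, offset: 240, alleles: [G, A], novelty: known}
  MSV9a:
    amplicon: F5
    offset: 262
    alleles: [G, A]
    genomic_positions: [7259758, 7791677]
    novelty: reference_paralog
  MSV10: {amplicon: F5, offset: 275, alleles: [G, A], novelty: known}
  MSV10a:
    amplicon: F5
    offset: 286
    alleles: [C, A]
    genomic_positions: [7259734, 7791701]
    novelty: novel
  MSV11: {amplicon: F6, offset: 50,  alleles: [C, T], novelty: known}
  MSV12: {amplicon: F6, offset: 85,  alleles: [C, T], novelty: known}
  MSV13: {amplicon: F6, offset: 120, alleles: [T, C], novelty: known}
  MSV14: {amplicon: F6, offset: 155, alleles: [C, A, G], novelty: known}
  MSV15: {amplicon: F6, offset: 190, alleles: [G, C, T], novelty: known}
  MSV16: {amplicon: F7, offset: 55,  alleles: [T], rsid: rs4840825, novelty: known}
  MSV17: {amplicon: F7, offset: 110, alleles: [C, T], novelty: known}
  MSV18: {amplicon: F7, offset: 165, alleles: [G, A], novelty: known}
  MSV19: {amplicon: F8, offset: 45,  alleles: [C, T], novelty: known}
  MSV20: {amplicon: F8, offset: 75,  alleles: [T, C], novelty: known}
  MSV21: {amplicon: F8, offset: 110, alleles: [A, T], novelty: known}
  MSV22: {amplicon: F8, offset: 140, alleles: [C, T], novelty: known}
  MSV23: {amplicon: F8, offset: 175, alleles: [C, T], novelty: known}
  MSV24: {amplicon: F8, offset: 210, alleles: [G, A], novelty: known}
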