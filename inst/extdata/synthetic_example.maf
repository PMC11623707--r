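##maf version=1 scoring=none
# synthetic alignment produced by mafkmer::generate_maf
a score=1.0
s hg38.chr1 0 67 + 10000000 CTTTTAG--CGTCTCATG-cTTATCCGTACGGCtTAGCAACCACTGacACT-CCCCTGAAANGG-ATTTTTT
s panTro6.chr1 0 68 - 10000000 GCTTTAGGGCGCCTCTGGTCTTATCCGTACGGCTTAG-a-CCtC-Ga-ACTCCTCCTGGAAGGGTcTGTTTT
s mm39.chr1 0 69 + 10000000 CNTTCAGcGCGTCTCA-NTCTTaTCAATACGGCTTAGCAAcCTCTGAAACTCCCCCTGAACGgGTCTG--TT
s rn7.chr1 0 69 + 10000000 CcTT-AGGgCGTCTCATGTCTTATCcGTACGGCTTAGCAACCTCTGTGa-TCCCNCTGAAAG-GTCTGTTTT

a score=2.0
s hg38.chr1 67 62 + 10000000 aCTGCTTATCtAgACGGATACTC-CTAGACGAATAACT-cCAGAGCTGATACANCAT-GTAGGTT
s panTro6.chr1 68 59 - 10000000 NCTGCTTATCTAGACGG-TACTCT--AGACGACTAAcTTCCA-AGCTGATCCACCAT-GTCGg-C
s mm39.chr1 69 63 - 10000000 A-TGNT-ATCTAGACTGATAcCCGcTAGACGACTTACTTCCAGAGCTGATCCACCATGGTAGGTT
s rn7.chr1 69 60 + 10000000 ACTGCATATCTTGACGGATACTCGC-AgA-GA-TAACTT-CAGA-CTGATCCACCaTAGTCGGCT

a score=3.0
s hg38.chr1 129 89 + 10000000 GA-GGTGTACTgGCATtTNACTTTTCGAANGCAATGGGCTT-CGACATTGA-TGAGTAT-AACCCTTTaCAGCTGCGCAAATTCGA-GCG-CCGA
s panTro6.chr1 127 90 - 10000000 GGAGGTGTACTGGCCTTTAACT-TTCgAACGCAATGGGATT-CGAcATAGAGTGAGT---AACCCTGTACCGCTTCGCAAACTCGAGGCGTCCGA
s mm39.chr1 132 93 + 10000000 GAAGTTTTACtGGCCTTTaACTcTTCGACCGCaATGGGATTACGACCTAGaGTG-GTATCAACCC-GTACAGCTTCGCAAACTGGAGGCNTCCGA
s rn7.chr1 129 90 + 10000000 GAAGG-GTACTGGCCTTTATCTC-TCg-ACGCAATGGGATTACAACATAGAGTGAG-ATCAACCCTGTACAGCTTCCAAAActCGAGGCCT-CGA

a score=4.0
s hg38.chr1 218 115 + 10000000 CTCGcTGGGtGNCACGCAAGTAGGCAAGTGA-CTCTGCA-CATATA-aTNCTCGGCTATTGATAGGCGGGAGGATACTATATGAtTTGCT-CCAACTTtCTAGTGGAGTGCGCCCTGCG
s panTro6.chr1 217 116 + 10000000 cTGGCTGGCTGCGACGCAAGTAGGCATGTGATCTCTGCAC-ATATATATGCTCGGCTATTGATAGGCGGGNGgGTACTATATGANTTGCTGCGAACTTTCAAGTGAAGTGCGCCCTG--
s mm39.chr1 225 113 + 10000000 CTCGCTGgCTGcCACGCaAT-AAGCAAGTGATCnCTGCT-CATATATAT-CtCGGCTATTGATAGGCGGGAGGATaCTATATGAATTGCTG-GAACTTT-TAGTG-AGNACGCCcTGCG
s rn7.chr1 219 116 + 10000000 CTCgCTGGCTGC-ACGCAAGTAGGAAAG-GaTCTCtGCATCAT-TAtATGCTCGgcTATTGATTGGCGGGAAGGTACTATATGaATTGCTGCGAACtTTCTAGAGGTGTGCGCcCTGCG

a score=5.0
s hg38.chr1 333 94 + 10000000 GGTGAcCGGACTTTAG-GGGAT-GTtTGGT-CGGTGGTCATTgGCTTCCTCAAATCTGTCAATCTCTGCTATGTAgTAAGAAAGGCATAaTTGCTgA
s panTro6.chr1 333 93 + 10000000 GGTGAC-GGACtCtaGTAGGATGGTTTGGTACGGTGGTCATTGGCTTCCTCAAATCTGT-AATcTCTGCTATGTAGTA-GAAAGGCa-AATTGCTGA
s mm39.chr1 338 91 - 10000000 GGTNG-GGGaCTTTAATAgGGT-GTTTGNTGCGGTgGTCANTGGCTtCCTCAAATC-GTCTATCACT-CTATGT-aTA-GAAAGGCATAATTGCNGa
s rn7.chr1 335 90 - 10000000 GGTGA-gGGGCTTTAGTGG-aTGGTT-GGTGCGGT-GTCATTGGCTTCCACA-atATGNcAATCACTGCTATGt-GTAAGGAAGG-ATAATTGCTGA

a score=6.0
s hg38.chr1 427 79 + 10000000 tCAATCTCNGGGCTGT-GACTgAcGTTCAACGAGGGTGTATgAAAATCGaCaTCATATTaGAACTCNA-CATCGGGGGGCC
s panTro6.chr1 426 79 + 10000000 TCAAtATCCGGG-TGCTGCCTGACGTTCACCGAGGGGGTATGAATaTcCAC-tCaTATGAGAACTCAAGCATCGGGGGGCC
s mm39.chr1 429 79 - 10000000 TCAATAGC-cgNCTGTTGCCTGACGTTCAC-GAGGGGGTATGAAAATCGACAtcAAANTAGAaCTCAGGCATCGGGGGGCC
s rn7.chr1 425 77 - 10000000 TCAATATC-gGGCAATTGCCTGaCCTTcACCAAGGTGGTAT-AAAATCGACATC-NATTAGAACTCAG-CATAGgGGTgCC

a score=7.0
s hg38.chr1 506 75 + 10000000 GNCTTTAGCACTCGAGCAACTTGAGATGTCCCTCCCTCGTTCGGGCGTaTGCGATGTTTCTCgCTGCGaNTATAA
s panTro6.chr1 505 75 - 10000000 GGCTTTGGGACTCGAGcAACTTGANAtGtCCCTCCCTCGTTCNGCCGTATGGGATGTTTCTCGcTGCGACTATAT
s mm39.chr1 508 73 + 10000000 GGCTCTAGAACtCGAGCCACT-GAGNTGTGcCTCCC-CGTTCGGACTTTTGCGATGtTNcTCGCTGcGACTaTAA
s rn7.chr1 502 70 + 10000000 GGC-TtGGC-CTNGaGCAaCTTGAgATGTCCCTCCCTCGA-CgGACGTNTT-GATG-TTCTCGCtGCGaCTATaA

a score=8.0
s hg38.chr1 581 78 - 10000000 G-aTtCGAGCGCGcCTGGACAAGATATGTTCAAtAAAAAACCGCTACCCAAGGGAgNACTCC-CGGAGgAATCGcGCATg
s panTro6.chr1 580 78 - 10000000 GgATCCGACCGAGCCTGGGCAAGATATgTTCAATACAAAACCGCTACGCAagGGAGTGCT-CCCGGaGCAAGAGCG-ATG
s mm39.chr1 581 78 + 10000000 TGATTCGAGCG-GCTTGGGCANNATATGTTCAATACNAAACCCC-ACCCAAGaGAGCCCTCcCCGGACCAATCGCGCATG
s rn7.chr1 572 77 + 10000000 GGATTCGAGCGA-CCTGGGCATGATATGTTCA-TACAAAACCGCtACCCaAGGGAGcGc-CCCNGGAGCCATCGCGCATG

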