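# Mature miRNA panel: conserved, tissue-representative miRNAs used for
# 7mer-A1 seed-match profiling of 3'UTRs.
# Sequences: curated mature (mouse) miRNA sequences, miRBase nomenclature.
# Columns: name <tab> mature_seq (RNA alphabet, 5'->3').
name	mature_seq
let-7a-5p	UGAGGUAGUAGGUUGUAUAGUU
miR-125b-5p	UCCCUGAGACCCUAACUUGUGA
miR-302a-3p	UAAGUGCUUCCAUGUUUUGGUGA
miR-1a-3p	UGGAAUGUAAAGAAGUAUGUAU
miR-150-5p	UCUCCCAACCCUUGUACCAGUG
miR-9-5p	UCUUUGGUUAUCUAGCUGUAUGA
miR-124-3p	UAAGGCACGCGGUGAAUGCC
miR-128-3p	UCACAGUGAACCGGUCUCUUU
miR-132-3p	UAACAGUCUACAGCCAUGGUCG
miR-138-5p	AGCUGGUGUUGUGAAUCAGGCCG
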