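# Curated phytohormone crosstalk fixture: pathways
UNIQUE-ID - PWY-ABA-BIO
COMMON-NAME - abscisic acid biosynthesis
//
UNIQUE-ID - PWY-AUXIN-HOMEOSTASIS
COMMON-NAME - auxin conjugate homeostasis (synthetic bridge pathway)
//
UNIQUE-ID - PWY-BRASSINOSTEROID-BIO-I
COMMON-NAME - brassinosteroid biosynthesis I
//
UNIQUE-ID - PWY-BRASSINOSTEROID-BIO-II
COMMON-NAME - brassinosteroid biosynthesis II
//
UNIQUE-ID - PWY-BRASSINOSTEROID-INACT
COMMON-NAME - brassinosteroid inactivation
//
UNIQUE-ID - PWY-CK-7N-GLUCOSIDE
COMMON-NAME - cytokinin 7-N-glucoside biosynthesis
//
UNIQUE-ID - PWY-CK-HOMEOSTASIS
COMMON-NAME - cytokinin conjugate homeostasis (synthetic bridge pathway)
//
UNIQUE-ID - PWY-CK-O-GLUCOSIDE
COMMON-NAME - cytokinin-O-glucoside biosynthesis
//
UNIQUE-ID - PWY-ETHYLENE-BIO-I
COMMON-NAME - ethylene biosynthesis I
//
UNIQUE-ID - PWY-FLAVONOL-BIO
COMMON-NAME - flavonol biosynthesis
//
UNIQUE-ID - PWY-GA-BIO-III
COMMON-NAME - gibberellin biosynthesis III (early C-13 hydroxylation)
//
UNIQUE-ID - PWY-GA-INACT-II
COMMON-NAME - gibberellin inactivation II (methylation)
//
UNIQUE-ID - PWY-IAA-BIO-I
COMMON-NAME - IAA biosynthesis I
//
UNIQUE-ID - PWY-IAA-CONJUGATE
COMMON-NAME - superpathway of IAA conjugate biosynthesis
//
UNIQUE-ID - PWY-IAA-DEG-V
COMMON-NAME - IAA degradation V
//
UNIQUE-ID - PWY-JA-BIO
COMMON-NAME - jasmonic acid biosynthesis
//
UNIQUE-ID - PWY-JA-CONJUGATES-I
COMMON-NAME - jasmonoyl-amino acid conjugates biosynthesis I
//
UNIQUE-ID - PWY-KAEMPFEROL-GLUCOSIDE
COMMON-NAME - kaempferol glucoside biosynthesis
//
UNIQUE-ID - PWY-PHE-DEG-III
COMMON-NAME - phenylalanine degradation III
//
UNIQUE-ID - PWY-QUERCETIN-GLUCOSIDE
COMMON-NAME - quercetin glucoside biosynthesis
//
UNIQUE-ID - PWY-QUERCETIN-SULFATE
COMMON-NAME - quercetin sulfate biosynthesis
//
UNIQUE-ID - PWY-SAM-CYCLE-II
COMMON-NAME - S-adenosyl-L-methionine cycle II
//
UNIQUE-ID - PWY-SA-BIO
COMMON-NAME - salicylic acid biosynthesis
//
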