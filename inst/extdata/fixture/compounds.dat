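# Curated phytohormone crosstalk fixture: compounds.
# SYNTHETIC-* compounds are documented placeholders (see README.md).
UNIQUE-ID - WATER
COMMON-NAME - water
//
UNIQUE-ID - PROTON
COMMON-NAME - H+
//
UNIQUE-ID - ATP
COMMON-NAME - ATP
//
UNIQUE-ID - ADP
COMMON-NAME - ADP
//
UNIQUE-ID - AMP
COMMON-NAME - AMP
//
UNIQUE-ID - PHOSPHATE
COMMON-NAME - phosphate
//
UNIQUE-ID - DIPHOSPHATE
COMMON-NAME - diphosphate
//
UNIQUE-ID - NAD
COMMON-NAME - NAD+
//
UNIQUE-ID - NADH
COMMON-NAME - NADH
//
UNIQUE-ID - NADP
COMMON-NAME - NADP+
//
UNIQUE-ID - NADPH
COMMON-NAME - NADPH
//
UNIQUE-ID - CARBON-DIOXIDE
COMMON-NAME - CO2
//
UNIQUE-ID - OXYGEN
COMMON-NAME - O2
//
UNIQUE-ID - CO-A
COMMON-NAME - coenzyme A
//
UNIQUE-ID - UDP
COMMON-NAME - UDP
//
UNIQUE-ID - CAMPEST-4-EN-3-ONE
COMMON-NAME - campest-4-en-3-one
//
UNIQUE-ID - HYDROXY-CAMPEST-4-EN-3-ONE
COMMON-NAME - (22alpha)-hydroxy-campest-4-en-3-one
//
UNIQUE-ID - CASTASTERONE
COMMON-NAME - castasterone
//
UNIQUE-ID - BRASSINOLIDE
COMMON-NAME - brassinolide
//
UNIQUE-ID - BRASSINOLIDE-GLUCOSIDE
COMMON-NAME - brassinolide glucoside
//
UNIQUE-ID - UDP-D-GLUCOSE
COMMON-NAME - UDP-D-glucose
//
UNIQUE-ID - TRANS-ZEATIN
COMMON-NAME - trans-zeatin
//
UNIQUE-ID - TRANS-ZEATIN-O-GLUCOSIDE
COMMON-NAME - trans-zeatin-O-glucoside
//
UNIQUE-ID - ZEATIN-DIGLUCOSIDE
COMMON-NAME - zeatin diglucoside
//
UNIQUE-ID - DIHYDROKAEMPFEROL
COMMON-NAME - dihydrokaempferol
//
UNIQUE-ID - KAEMPFEROL
COMMON-NAME - kaempferol
//
UNIQUE-ID - TRANS-DIHYDROQUERCETIN
COMMON-NAME - trans-dihydroquercetin
//
UNIQUE-ID - QUERCETIN
COMMON-NAME - quercetin
//
UNIQUE-ID - KAEMPFEROL-3-GLUCOSIDE
COMMON-NAME - kaempferol 3-glucoside
//
UNIQUE-ID - QUERCETIN-3-GLUCOSIDE
COMMON-NAME - quercetin 3-glucoside
//
UNIQUE-ID - QUERCETIN-3-METHYL-ETHER
COMMON-NAME - quercetin 3-methyl ether
//
UNIQUE-ID - KAEMPFEROL-METHYL-ETHER
COMMON-NAME - kaempferol methyl ether
//
UNIQUE-ID - S-ADENOSYL-L-METHIONINE
COMMON-NAME - S-adenosyl-L-methionine
//
UNIQUE-ID - S-ADENOSYL-L-HOMOCYSTEINE
COMMON-NAME - S-adenosyl-L-homocysteine
//
UNIQUE-ID - GIBBERELLIN-A12
COMMON-NAME - gibberellin A12
//
UNIQUE-ID - GIBBERELLIN-A15
COMMON-NAME - gibberellin A15
//
UNIQUE-ID - GIBBERELLIN-A19
COMMON-NAME - gibberellin A19
//
UNIQUE-ID - GIBBERELLIN-A20
COMMON-NAME - gibberellin A20
//
UNIQUE-ID - GA20-METHYL-ESTER
COMMON-NAME - gibberellin A20 methyl ester
//
UNIQUE-ID - INDOLE-3-ACETALDEHYDE
COMMON-NAME - indole-3-acetaldehyde
//
UNIQUE-ID - INDOLE-3-ACETATE
COMMON-NAME - indole-3-acetate
//
UNIQUE-ID - METHYL-INDOLE-3-ACETATE
COMMON-NAME - methyl indole-3-acetate
//
UNIQUE-ID - INDOLE-3-ACETYL-GLUCOSE
COMMON-NAME - indole-3-acetyl-beta-1-D-glucose
//
UNIQUE-ID - INDOLE-3-ACETYL-PHENYLALANINE
COMMON-NAME - indole-3-acetyl-phenylalanine
//
UNIQUE-ID - L-PHENYLALANINE
COMMON-NAME - L-phenylalanine
//
UNIQUE-ID - KETO-PHENYLPYRUVATE
COMMON-NAME - keto-phenylpyruvate
//
UNIQUE-ID - L-GLUTAMATE
COMMON-NAME - L-glutamate
//
UNIQUE-ID - 2-OXOGLUTARATE
COMMON-NAME - 2-oxoglutarate
//
UNIQUE-ID - ACC
COMMON-NAME - 1-aminocyclopropane-1-carboxylate
//
UNIQUE-ID - JASMONATE
COMMON-NAME - jasmonate
//
UNIQUE-ID - JASMONOYL-ACC
COMMON-NAME - jasmonoyl-ACC
//
UNIQUE-ID - L-ASCORBATE
COMMON-NAME - L-ascorbate
//
UNIQUE-ID - ETHYLENE
COMMON-NAME - ethylene
//
UNIQUE-ID - METHYLTHIOADENOSINE
COMMON-NAME - 5-methylthioadenosine
//
UNIQUE-ID - VIOLAXANTHIN-9-CIS
COMMON-NAME - 9-cis-violaxanthin
//
UNIQUE-ID - XANTHOXIN
COMMON-NAME - xanthoxin
//
UNIQUE-ID - CHORISMATE
COMMON-NAME - chorismate
//
UNIQUE-ID - ISOCHORISMATE
COMMON-NAME - isochorismate
//
UNIQUE-ID - LINOLENATE
COMMON-NAME - alpha-linolenate
//
UNIQUE-ID - 13-HPOT
COMMON-NAME - 13(S)-hydroperoxy-octadecatrienoate
//
UNIQUE-ID - ETHANOL
COMMON-NAME - ethanol
//
UNIQUE-ID - ACETALDEHYDE
COMMON-NAME - acetaldehyde
//
UNIQUE-ID - GLUTATHIONE
COMMON-NAME - glutathione
//
UNIQUE-ID - XENOBIOTIC
COMMON-NAME - xenobiotic substrate
//
UNIQUE-ID - GS-CONJUGATE
COMMON-NAME - glutathione S-conjugate
//
UNIQUE-ID - 4-COUMAROYL-COA
COMMON-NAME - 4-coumaroyl-CoA
//
UNIQUE-ID - MALONYL-COA
COMMON-NAME - malonyl-CoA
//
UNIQUE-ID - NARINGENIN-CHALCONE
COMMON-NAME - naringenin chalcone
//
UNIQUE-ID - CELLULOSE
COMMON-NAME - cellulose
//
UNIQUE-ID - SYNTHETIC-LINK-04-05
COMMON-NAME - synthetic linking metabolite (route steps 4-5)
//
UNIQUE-ID - SYNTHETIC-LINK-07-08
COMMON-NAME - synthetic linking metabolite (route steps 7-8)
//
UNIQUE-ID - SYNTHETIC-LINK-09-10
COMMON-NAME - synthetic linking metabolite (route steps 9-10)
//
UNIQUE-ID - SYNTHETIC-LINK-11-12
COMMON-NAME - synthetic linking metabolite (route steps 11-12)
//
UNIQUE-ID - SYNTHETIC-PRE-04
COMMON-NAME - synthetic precursor (step 4 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-POST-05
COMMON-NAME - synthetic product (step 5 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-PRE-07
COMMON-NAME - synthetic precursor (step 7 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-POST-08
COMMON-NAME - synthetic product (step 8 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-PRE-09
COMMON-NAME - synthetic precursor (step 9 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-POST-10
COMMON-NAME - synthetic product (step 10 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-PRE-11
COMMON-NAME - synthetic precursor (step 11 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-POST-12
COMMON-NAME - synthetic product (step 12 placeholder reaction)
//
UNIQUE-ID - SYNTHETIC-AC-01-SUB
COMMON-NAME - synthetic bridge substrate 01
//
UNIQUE-ID - SYNTHETIC-AC-01-PROD
COMMON-NAME - synthetic bridge product 01
//
UNIQUE-ID - SYNTHETIC-AC-02-SUB
COMMON-NAME - synthetic bridge substrate 02
//
UNIQUE-ID - SYNTHETIC-AC-02-PROD
COMMON-NAME - synthetic bridge product 02
//
UNIQUE-ID - SYNTHETIC-AC-03-SUB
COMMON-NAME - synthetic bridge substrate 03
//
UNIQUE-ID - SYNTHETIC-AC-03-PROD
COMMON-NAME - synthetic bridge product 03
//
UNIQUE-ID - SYNTHETIC-AC-04-SUB
COMMON-NAME - synthetic bridge substrate 04
//
UNIQUE-ID - SYNTHETIC-AC-04-PROD
COMMON-NAME - synthetic bridge product 04
//
UNIQUE-ID - SYNTHETIC-AC-05-SUB
COMMON-NAME - synthetic bridge substrate 05
//
UNIQUE-ID - SYNTHETIC-AC-05-PROD
COMMON-NAME - synthetic bridge product 05
//
UNIQUE-ID - SYNTHETIC-AC-06-SUB
COMMON-NAME - synthetic bridge substrate 06
//
UNIQUE-ID - SYNTHETIC-AC-06-PROD
COMMON-NAME - synthetic bridge product 06
//
UNIQUE-ID - SYNTHETIC-AC-07-SUB
COMMON-NAME - synthetic bridge substrate 07
//
UNIQUE-ID - SYNTHETIC-AC-07-PROD
COMMON-NAME - synthetic bridge product 07
//
UNIQUE-ID - SYNTHETIC-AC-08-SUB
COMMON-NAME - synthetic bridge substrate 08
//
UNIQUE-ID - SYNTHETIC-AC-08-PROD
COMMON-NAME - synthetic bridge product 08
//
UNIQUE-ID - SYNTHETIC-AC-09-SUB
COMMON-NAME - synthetic bridge substrate 09
//
UNIQUE-ID - SYNTHETIC-AC-09-PROD
COMMON-NAME - synthetic bridge product 09
//
UNIQUE-ID - SYNTHETIC-AC-10-SUB
COMMON-NAME - synthetic bridge substrate 10
//
UNIQUE-ID - SYNTHETIC-AC-10-PROD
COMMON-NAME - synthetic bridge product 10
//
UNIQUE-ID - SYNTHETIC-AC-11-SUB
COMMON-NAME - synthetic bridge substrate 11
//
UNIQUE-ID - SYNTHETIC-AC-11-PROD
COMMON-NAME - synthetic bridge product 11
//
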