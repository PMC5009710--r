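hormone	pathway_id	role
abscisic acid	PWY-ABA-BIO	biosynthesis
auxin	PWY-IAA-BIO-I	biosynthesis
auxin	PWY-IAA-CONJUGATE	conjugation
auxin	PWY-IAA-DEG-V	degradation
auxin	PWY-AUXIN-HOMEOSTASIS	conjugation
brassinosteroid	PWY-BRASSINOSTEROID-BIO-I	biosynthesis
brassinosteroid	PWY-BRASSINOSTEROID-BIO-II	biosynthesis
brassinosteroid	PWY-BRASSINOSTEROID-INACT	inactivation
cytokinin	PWY-CK-O-GLUCOSIDE	conjugation
cytokinin	PWY-CK-7N-GLUCOSIDE	conjugation
cytokinin	PWY-CK-HOMEOSTASIS	conjugation
ethylene	PWY-ETHYLENE-BIO-I	biosynthesis
gibberellin	PWY-GA-BIO-III	biosynthesis
gibberellin	PWY-GA-INACT-II	inactivation
jasmonic acid	PWY-JA-BIO	biosynthesis
jasmonic acid	PWY-JA-CONJUGATES-I	conjugation
salicylic acid	PWY-SA-BIO	biosynthesis
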