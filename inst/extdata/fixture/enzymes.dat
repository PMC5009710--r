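# Curated phytohormone crosstalk fixture: enzymes (keyed by EC string).
UNIQUE-ID - 1.3.1.-
COMMON-NAME - oxidoreductase (steroid reductase family)
GENE - AT3G55360
//
UNIQUE-ID - 1.14.13.-
COMMON-NAME - NADPH-dependent monooxygenase family
GENE - AT3G50660
GENE - AT1G16400
GENE - AT2G27690
//
UNIQUE-ID - 2.4.1.-
COMMON-NAME - hexosyltransferase family
GENE - AT5G17050
GENE - AT1G06000
//
UNIQUE-ID - 2.4.1.203
COMMON-NAME - trans-zeatin O-beta-D-glucosyltransferase
GENE - AT1G22400
//
UNIQUE-ID - 1.14.11.23
COMMON-NAME - flavonol synthase
GENE - AT5G08640
GENE - AT4G25420
GENE - AT4G22880
//
UNIQUE-ID - 2.1.1.-
COMMON-NAME - methyltransferase family
GENE - AT5G54160
GENE - AT3G63410
//
UNIQUE-ID - 1.14.11.-
COMMON-NAME - 2-oxoglutarate-dependent dioxygenase family
GENE - AT1G80340
GENE - AT1G15550
GENE - AT1G47990
GENE - AT1G14130
//
UNIQUE-ID - 1.2.3.7
COMMON-NAME - indole-3-acetaldehyde oxidase
GENE - AT5G20960
GENE - AT2G27150
//
UNIQUE-ID - 2.4.1.121
COMMON-NAME - indole-3-acetate beta-glucosyltransferase
GENE - AT4G15550
//
UNIQUE-ID - 6.3.-.-
COMMON-NAME - GH3 amido synthetase / ligase family
GENE - AT4G27260
GENE - AT5G54510
GENE - AT1G28130
GENE - AT2G46370
//
UNIQUE-ID - 2.6.1.57
COMMON-NAME - aromatic-amino-acid transaminase
GENE - AT1G70560
GENE - AT1G62960
GENE - AT5G51690
//
UNIQUE-ID - 4.4.1.14
COMMON-NAME - 1-aminocyclopropane-1-carboxylate synthase
GENE - AT1G01480
GENE - AT4G11280
GENE - AT4G37770
//
UNIQUE-ID - 1.14.17.4
COMMON-NAME - aminocyclopropanecarboxylate oxidase (ACO)
GENE - AT2G19590
GENE - AT1G62380
//
UNIQUE-ID - 2.6.1.5
COMMON-NAME - tyrosine aminotransferase
GENE - AT2G24850
GENE - AT2G20610
//
UNIQUE-ID - 4.1.1.50
COMMON-NAME - S-adenosylmethionine decarboxylase
GENE - AT5G18930
//
UNIQUE-ID - 2.8.1.9
COMMON-NAME - molybdenum cofactor sulfurase
GENE - AT1G16540
//
UNIQUE-ID - 1.13.11.51
COMMON-NAME - 9-cis-epoxycarotenoid dioxygenase
GENE - AT1G78390
//
UNIQUE-ID - 5.4.4.2
COMMON-NAME - isochorismate synthase
GENE - AT1G74710
//
UNIQUE-ID - 2.3.1.74
COMMON-NAME - naringenin-chalcone synthase
GENE - AT5G13930
//
UNIQUE-ID - 1.13.11.12
COMMON-NAME - lipoxygenase
GENE - AT3G45140
GENE - AT1G17420
//
UNIQUE-ID - 1.1.1.1
COMMON-NAME - alcohol dehydrogenase
GENE - AT1G77120
//
UNIQUE-ID - 2.5.1.18
COMMON-NAME - glutathione transferase
GENE - AT2G47730
//
UNIQUE-ID - 2.4.1.12
COMMON-NAME - cellulose synthase
GENE - AT5G17420
//
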