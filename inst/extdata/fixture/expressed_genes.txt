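# Root stele (vasculature) expressed-gene list for the fixture.
# Enzyme-encoding genes (route steps; the trans-zeatin O-glucosyltransferase
# gene AT1G22400 is deliberately absent).
AT3G55360
AT2G27690
AT1G06000
AT5G17050
AT5G08640
AT4G25420
AT3G63410
AT5G54160
AT1G14130
AT1G80340
AT2G27150
AT5G20960
AT4G15550
AT2G46370
AT4G27260
AT5G54510
AT1G62960
AT1G70560
AT1G01480
AT4G11280
AT4G37770
AT1G62380
AT2G19590
# Expressed transcription factors
AT1G73730
AT1G75080
AT2G03220
AT3G18990
AT4G34990
AT5G11260
AT2G47460
AT2G01570
AT1G14920
AT4G36930
AT4G25490
AT3G61850
AT5G20730
AT1G19850
AT5G62000
AT3G20770
AT3G01470
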