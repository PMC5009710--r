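# Root proteome detected-protein list for the fixture (gene loci).
AT3G55360
AT1G06000
AT3G63410
AT5G51690
AT4G15550
AT2G19590
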