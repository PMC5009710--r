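# The 13 enzymes of the consecutive metabolic route, in step order.
1.3.1.-
1.14.13.-
2.4.1.-
2.4.1.203
1.14.11.23
2.1.1.-
1.14.11.-
1.2.3.7
2.4.1.121
6.3.-.-
2.6.1.57
4.4.1.14
1.14.17.4
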