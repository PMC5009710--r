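tf_gene_id	target_gene_id
AT2G20180	AT1G78390
AT3G26790	AT1G78390
AT3G26790	AT1G80340
AT2G01570	AT1G80340
AT2G01570	AT4G25420
AT4G08150	AT4G25420
AT4G08150	AT1G47990
AT1G62360	AT1G47990
AT1G62360	AT1G15550
AT4G18960	AT1G15550
AT4G18960	AT9G90101
AT3G61850	AT9G90101
AT3G61850	AT9G90102
AT4G25490	AT9G90102
AT4G25490	AT9G90103
AT4G36930	AT9G90103
AT4G36930	AT9G90104
AT1G28300	AT9G90104
AT1G28300	AT9G90105
AT5G13790	AT9G90105
AT5G13790	AT9G90106
AT3G61890	AT9G90106
AT3G61890	AT9G90107
AT1G14920	AT9G90107
AT1G14920	AT9G90108
AT2G20180	AT9G90108
AT2G20180	AT4G27260
AT5G37020	AT4G27260
AT5G37020	AT1G28130
AT3G51060	AT1G28130
AT3G51060	AT9G90201
AT1G77850	AT9G90201
AT1G77850	AT9G90202
AT5G20730	AT9G90202
AT5G20730	AT9G90203
AT2G20180	AT9G90203
AT1G67260	AT3G50660
AT2G20180	AT3G50660
AT2G20180	AT9G90301
AT1G75080	AT9G90301
AT1G75080	AT9G90302
AT1G67260	AT9G90302
AT1G19850	AT4G37770
AT3G59060	AT4G37770
AT3G59060	AT9G90401
AT5G62000	AT9G90401
AT5G62000	AT9G90402
AT1G28300	AT9G90402
AT1G28300	AT9G90403
AT1G19850	AT9G90403
AT5G01900	AT3G45140
AT2G24570	AT3G45140
AT2G24570	AT2G24850
AT1G52890	AT2G24850
AT1G52890	AT9G90501
AT1G32640	AT9G90501
AT1G32640	AT9G90502
AT3G15500	AT9G90502
AT3G15500	AT9G90503
AT4G31550	AT9G90503
AT4G31550	AT9G90504
AT5G01900	AT9G90504
AT1G27730	AT1G17420
AT1G74930	AT1G17420
AT1G74930	AT9G90601
AT1G32640	AT9G90601
AT1G32640	AT9G90602
AT1G62300	AT9G90602
AT1G62300	AT9G90603
AT2G03340	AT9G90603
AT2G03340	AT9G90604
AT1G27730	AT9G90604
AT1G45249	AT1G77120
AT1G35515	AT1G77120
AT1G35515	AT9G90701
AT2G47190	AT9G90701
AT2G47190	AT9G90702
AT4G25470	AT9G90702
AT4G25470	AT9G90703
AT1G53910	AT9G90703
AT1G53910	AT9G90704
AT1G32640	AT9G90704
AT1G32640	AT9G90705
AT1G45249	AT9G90705
AT5G35550	AT4G22880
AT5G13930	AT4G22880
AT5G13930	AT9G90801
AT4G38620	AT9G90801
AT4G38620	AT5G13930
AT2G47460	AT5G13930
AT2G47460	AT5G17050
AT4G34990	AT5G17050
AT4G34990	AT9G90802
AT1G02340	AT9G90802
AT1G02340	AT9G90803
AT5G11260	AT9G90803
AT5G11260	AT9G90804
AT1G09530	AT9G90804
AT1G09530	AT9G90805
AT2G43010	AT9G90805
AT2G43010	AT9G90806
AT3G17609	AT9G90806
AT3G17609	AT9G90807
AT1G63650	AT9G90807
AT1G63650	AT9G90808
AT5G41315	AT9G90808
AT5G41315	AT9G90809
AT1G56650	AT9G90809
AT1G56650	AT9G90810
AT5G35550	AT9G90810
AT3G28910	AT1G74710
AT3G20770	AT1G74710
AT3G20770	AT2G19590
AT2G27050	AT2G19590
AT2G27050	AT9G90901
AT1G10170	AT9G90901
AT1G10170	AT9G90902
AT3G01470	AT9G90902
AT3G01470	AT9G90903
AT3G28910	AT9G90903
AT3G01470	AT2G19590
AT3G50410	AT2G47730
AT3G16770	AT2G47730
AT3G16770	AT9G91001
AT1G69120	AT9G91001
AT1G69120	AT9G91002
AT3G50410	AT9G91002
AT5G60890	AT2G20610
AT5G61420	AT2G20610
AT3G13890	AT5G17420
AT1G71930	AT5G17420
AT5G07690	AT1G16400
AT1G73730	AT1G16400
AT1G16490	AT5G54160
AT1G79180	AT5G54160
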