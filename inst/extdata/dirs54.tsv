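0.395660854751	-0.136363928475	0.908216585969
-0.775081694312	0.56984407263	0.272994688648
-0.877340751384	-0.449828508071	0.167115287413
-0.77720522163	-0.395031629951	0.489797973464
-0.141980352349	-0.663504961787	-0.734576575471
-0.62911388419	-0.711770231154	0.312408160525
-0.668447175945	0.267464305649	0.694003759482
-0.467258836508	-0.527291454763	-0.709670981117
-0.232033420552	0.671011503226	0.704204554292
0.738968440205	0.366011639702	0.565651062037
0.864872423583	-0.262515544259	-0.427879983112
0.859031606956	0.472808486829	0.196257058555
0.638152442281	-0.275030120367	0.719110487549
0.0367500015339	-0.911125658552	0.410486871551
-0.345161883705	0.791571510412	-0.504259673125
0.538111904641	0.312789797475	-0.782686476617
-0.0328389355784	-0.994650649309	0.0979371744482
-0.0613290060181	0.698304565629	-0.71316862427
-0.108447509295	-0.0048670461897	-0.994090262295
0.584250821032	-0.805637538078	-0.0979751772758
-0.314198802049	-0.281499486633	-0.906662644988
-0.379148247866	0.400683245783	0.834086052328
-0.0554779191983	0.869402627727	0.490979909348
-0.939029157556	-0.0919718592786	0.331308645165
0.923299458658	0.177751508254	0.340473950479
-0.19201325329	0.141346900527	0.971160112583
-0.00440982775408	0.419708428354	0.90764827361
-0.823239669931	0.0456483069152	-0.565855704158
0.967643809344	-0.224517701873	-0.115140174498
-0.224084075629	-0.213226096951	0.950957916329
0.41701727481	-0.811477790237	-0.409390264249
0.965395439532	-0.149446411585	0.213722753573
0.440978719352	0.886611612765	0.139490563085
-0.602450256436	-0.13089480184	-0.787350137722
0.696986679467	0.716897640134	0.0163506029177
-0.356664401664	0.506942052033	-0.784729418631
-0.234227944209	0.959283770708	0.157835095618
-0.854190792293	0.516483657312	-0.0600226798047
0.0861174614026	-0.363339391873	0.927668189147
0.498495431013	-0.0213432762814	-0.866629545894
0.602187420832	-0.581564382154	0.54694897349
0.226676203502	0.540762747807	-0.810057744454
0.640016029454	-0.731043801121	0.236546914763
-0.632227797368	-0.667478337677	-0.393396340816
-0.771568053799	-0.0683009829963	0.632469536087
0.988554576595	0.150848013872	-0.00217389161352
-0.830311443772	0.392064837128	-0.396065739276
0.358301026174	0.911698486531	-0.201062786959
-0.126569642434	-0.96672258338	-0.222323126095
0.261394800745	0.809109510416	-0.526321725087
0.590140312163	-0.574757826822	-0.566910797628
-0.514170416016	-0.603860994502	0.609081835727
-0.339583657128	0.924727382613	-0.171936638495
-0.328566479501	-0.810305953091	-0.485230183454
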