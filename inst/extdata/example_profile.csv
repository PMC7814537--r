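# alphabet=ACGT-
0.94979424267401669,0.00017151778151772826,2.3457223515061548e-07,0.049652042175330459,0.00038196279689993825
0.882005176200646,0.010593164292103583,0.046075799471843641,5.9656313475623173e-16,0.061325860035406125
0.99942374280288693,6.2837641917812834e-16,2.7806041996567303e-05,6.7652549746218234e-08,0.00054838350256622274
0.97028864165204942,2.6005931406932548e-06,4.352132116936187e-07,0.0022403211378634312,0.027468001403734656
0.99939379363456959,2.5381577486078589e-06,4.1706414384644096e-06,8.8775702984705471e-05,0.00051072186325874151
0.95358590348716987,2.6100836252730841e-05,0.032770542474464294,7.7661558036564915e-05,0.013539791644076565
0.99472270937120477,0.00045556295884639363,0.00080068000752591838,0.0039991503574942156,2.189730492872161e-05
0.98485356231518895,0.013934324284630243,0.001182000015950086,6.3353529855267507e-06,2.3778031245088377e-05
0.0013991374372907259,2.5586163517417554e-08,0.018976606003921901,0.03508810130392713,0.94453612966869671
2.3244179041689923e-06,0.0049901367343087102,0.042385139106188748,1.9082776516097396e-06,0.95262049146394678
0.13033687185920406,0.86849140502867328,0.00094583479742608686,0.00022327880471747526,2.6095099790082967e-06
0.049109811187642211,0.89950425688067404,0.048414640450686497,0.0029605734379431351,1.0718043054188064e-05
0.0040666487131524607,0.97061447201515083,0.00013014446027607323,0.024572811371215562,0.00061592344020499734
0.00014526246846028739,0.90454058413784555,0.04005151912636544,0.00012795248358869613,0.055134681783740001
0.03558998911113704,0.91582845623721554,0.00057685189656836097,0.04360160517734165,0.0044030975777373605
0.048044975253259146,0.94981755813645075,0.00053742009397581632,0.00097153148540591661,0.00062851503090839451
0.060228315826727691,0.87986129780309952,2.9372570171843867e-07,0.040526107315387021,0.019383985329084055
0.0094722763723673938,0.97412925808947526,0.00016448775946891354,3.9176127013813999e-08,0.016233938602561421
0.0016147611991223941,0.99165131892194314,0.0028121499481349593,1.0327824956400537e-05,0.0039114421058430151
4.7707429854667506e-07,0.98637417606816558,2.5046989148922313e-05,0.013436400207904303,0.00016389966048255565
2.4173053743340668e-06,0.99286615275427947,0.0060224617296137962,1.4101628093809276e-06,0.0011075580479229805
0.0098301490568776743,0.86739898614621824,0.0192277527848186,4.5811233389458143e-08,0.10354306620085213
0.0064272798994238489,0.88412535767918776,0.027363601960511724,8.2731894381268555e-07,0.08208293314193281
8.3374107259022534e-06,0.9766035548119385,0.02119084020675133,1.9719208155502267e-05,0.0021775483624288201
0.028990835233913426,0.95428506225444831,0.004191119704912618,1.3304829300232378e-05,0.012519677977425496
0.037302440156123724,0.78433515605357007,3.3655633334874496e-05,0.17419443883319105,0.0041343093237803672
0.0042098572285639325,0.051506618200527154,0.0082118913324632399,0.0067366737261653946,0.92933495951228029
3.2346336063134859e-05,0.019195986269835045,0.019216140478384727,0.00016226296478300767,0.96139326395093416
1.4073744958285001e-10,1.7980103352021653e-07,0.00012533638111815641,0.0031763521381142942,0.99669813153899656
5.6212158945652678e-07,0.1544301366459768,0.041783113766525173,0.0051073220009154058,0.79867886546499323
0.020335337334074284,1.7958684205176449e-10,0.031945438924933102,0.024735208447131524,0.9229840151142743
0.0085270813881165013,8.9471886762069859e-05,0.0011757820791595968,1.4259317452642752e-07,0.99020752205278739
2.5719985617753837e-05,0.00036589719941911188,8.1587977996020031e-06,0.0040141771086713322,0.99558604690849217
0.00055071001780361377,0.0011822183975210168,0.005872252439714289,0.0020509505424412436,0.99034386860251988
0.0011776786519220621,0.00074018958615291877,9.0890985750997436e-05,1.1404220002198342e-06,0.99799010035417379
0.0090072640967116396,0.0024438774082079359,0.0025776425706688891,7.1439768280291635e-07,0.98597050152672872
0.10964190838000179,5.0548179490561795e-05,8.4730531744228358e-05,1.0270924378200806e-07,0.8902227101995196
5.6914400166748422e-05,0.05381688355073224,7.2736647237096755e-07,6.6040450862566422e-05,0.94605943423176608
0.00030155437475828576,3.1986727317214814e-08,0.0057537116697928938,0.11655403971514378,0.87739066225357776
0.031411409958446747,0.046732576268984527,5.8827412415298633e-05,0.039934436179207194,0.88186275018094629
0.0099424673944667353,3.7768039352374589e-06,0.89759558576450216,0.0083228056146857909,0.084135364422410194
0.0059337172889643349,0.019372734496538042,0.90823489271708546,0.00013900875348894358,0.06631964674392328
1.1199207583795312e-07,3.3000307772008111e-05,0.99729862854698337,4.5754273855843584e-05,0.0026225048793129344
0.011429285099224236,1.3163291739333547e-05,0.9565113107298534,0.016850482894295339,0.015195757984887558
0.0018328324443683138,0.13836599754123943,3.1215049392959426e-06,7.5844103783093597e-08,0.8597979726653493
8.8605149353743101e-05,0.020212206745155323,1.668200455054758e-16,6.3988475402556708e-11,0.97969918804150224
0.0039302210571737356,0.019349323527755796,5.3969713137702588e-05,0.97656303108182763,0.00010345462010511262
0.0020584556593950154,5.731775559162101e-05,8.0532726167213499e-05,0.99759026204735579,0.00021343181149032544
0.0065569756775193137,1.6312488361451621e-09,2.0226431920872653e-05,0.9933942008775084,2.8595381802630625e-05
2.0314895791228353e-16,0.00027489565269946478,0.0005879403540501603,0.99823853737388868,0.00089862661936150829
9.3864373166062552e-05,3.8147904037185823e-05,0.025759943572895232,0.078657038387282163,0.89545100576261938
4.4008349522368287e-06,0.040847804855699936,0.0034343834045390356,0.00070537063502701597,0.9550080402697817
0.0033913883868444909,0.042145661076711749,0.026074542860112203,2.9839453825436693e-08,0.92838837783687767
1.5054161864255421e-05,0.016532591624240915,0.017805387048389482,0.0012647300424190114,0.96438223712308635
0.98990904391147394,2.0895843942814348e-08,7.688215333411968e-06,6.3344195000011578e-06,0.010076912557848672
0.97208321406113973,5.9135078291706404e-06,0.00017153377500945342,0.027725277494473535,1.4061161548113939e-05
0.96123057881768348,1.8156684207212331e-05,0.03372225771106302,0.0011427838130964546,0.0038862229739497216
0.99812233654425908,4.2462252944998466e-06,0.0017690488516049663,4.9013400840123626e-05,5.5354978001237624e-05
0.97363259314135553,0.020147404291698884,0.0021533980672106771,4.6496309435634664e-05,0.0040201081902992899
0.96807184449298334,4.1661040763955977e-10,0.000344776222232205,0.031571417049786159,1.1961818387882176e-05
0.0045558213900900799,0.0081735406140943274,0.059882321947308484,0.032024093652936229,0.89536422239557101
0.010403969903528017,0.029466994454170198,0.00045258933579838724,0.010506081816157802,0.94917036449034553
1.395549125193167e-06,2.8122550907362989e-09,0.021325912253286738,0.012983045704856167,0.96568964368047683
0.021778443162913084,0.88862804673288709,6.4500424337959411e-07,0.070203073846382191,0.019389791253574346
8.888042679831698e-06,0.99998907827328232,5.3421426547385541e-07,1.4931364046552027e-06,6.3333677518409369e-09
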