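sample_id	cg00000001	cg00000002	cg00000003	cg00000004	cg00000005	cg00000006	cg00000007	cg00000008	cg00000009	cg00000010	cg00000011	cg00000012
brain_h001	0.6755439307598178	0.6839436027368844	0.0627565145754678	0.6374220152586915	0.8240229925699912	0.0657031860561217	0.3305524792421884	0.5972668574162239	0.5486256611668882	0.2860997964350450	0.2078044078401975	0.2424092252108220
brain_h002	0.6486890276017639	0.8640470937510316	0.0925923999239215	0.6944321729263742	0.6363221293257196	0.0676040038164954	0.3349445715901870	0.6616770589570384	0.5918600594556616	0.2730795476247572	0.2045998094654537	0.1793646355813304
brain_h003	0.7510960789953463	0.6962019315234187	0.1559973034308160	0.7713262764708263	0.7825172757260104	0.0796626104328226	0.2687814386431345	0.6766001961553112	0.5424021016558982	0.2477616345534688	0.1042201453213974	0.2122906843781684
brain_h004	0.6447743507730637	0.7196834462868505	0.1464735238609406	0.6939019867067644	0.7438314612617641	0.1562586542301325	0.3130166597075791	0.7347271279497181	0.3929769409121262	0.2991411167996414	0.3070714513296743	0.1837385010621028
brain_h005	0.7073112427361454	0.7531815571037344	0.0658255772156262	0.6493401903850047	0.8357284392717882	0.1627719925732281	0.3659250436211241	0.5129038126655338	0.5446451971652523	0.2858374934494571	0.3127028311972040	0.1538353109097549
brain_h006	0.7156427261734878	0.7716046427821880	0.0664773836497797	0.6326896134726153	0.8011492955487183	0.0761268489988908	0.2521949465574045	0.5715053504135812	0.3849458752050300	0.3633394564895465	0.3070470130450555	0.0704918894704045
brain_d001	0.4504533665185169	0.5954084608139819	0.1485577288405996	0.7539971061316751	0.7581938081125240	0.0848633249141285	0.3322863437839167	0.4199600615870184	0.6166502423171131	0.3482977002361683	0.1798832682636091	0.1246834230301690
brain_d002	0.3438199866327059	0.7695441152872363	0.1147855818381670	0.6750959801520706	0.7991482791485773	0.0881845537864422	0.5192423725105907	0.3419731691756843	0.6068861079981559	0.3676901121887111	0.3070909412224661	0.1801157114544546
brain_d003	0.4874470287584957	0.7129777038121352	0.0753838133564305	0.6720108360502602	0.7942029276023640	0.1129950217731574	0.2247973810895058	0.3632868463189964	0.6292168185959255	0.3309027064240271	0.2577881671547645	0.1838486929553992
brain_d004	0.4618919923453216	0.8012255004961827	0.1158567276945190	0.6898812562764405	0.7624196175902226	0.1166304081843967	0.5743710182907640	0.4925865291908940	0.5443394775885688	0.4435166341580240	0.2202106633659731	0.1214600006003763
brain_d005	0.3264680422889111	0.7363378058301520	0.1501687463964603	0.6997937444362662	0.7496847967128031	0.1100145176096809	0.3012006398308262	0.4776712755000205	0.5657511969780521	0.2304507904368194	0.1803950226867580	0.1447490015169615
brain_d006	0.3704207252186091	0.7947452616132138	0.0858330788171377	0.5930582298512348	0.7719566952688601	0.0469377578739601	0.2144000127675529	0.3995204310289752	0.3166204705707737	0.3724259747770711	0.2409619469407441	0.1709428182199237
kidney_h001	0.4206663719627889	0.8222571364165746	0.1378347696316925	0.9434710304291626	0.8288524355587512	0.0385701883193039	0.4081653140031630	0.1905170470561881	0.8790184887835986	0.2294522847986717	0.2005594871143213	0.0749857355222211
kidney_h002	0.3471503032010423	0.8129962797714884	0.1464586273078411	0.9257912549697248	0.7573529637451952	0.1759867387232212	0.1785718599458664	0.3372481607853308	0.7113101165190943	0.3813525393217779	0.1668283411552597	0.1022193078697180
kidney_h003	0.3146140043279271	0.8179345605411572	0.0549828871872232	0.9540960848046807	0.7957499582833456	0.0908012795145940	0.4541477234037475	0.3530634566313317	0.8545100366649111	0.3419300944399389	0.2737688020166156	0.1127448986563755
kidney_h004	0.4107364861286756	0.6270748438171008	0.1158277363647560	0.9579327875154856	0.7991275536856963	0.1205047347826642	0.3135243699421918	0.4250037296122570	0.7954983774281447	0.1788017003757488	0.3174896910959896	0.2348391088078963
kidney_h005	0.3824850517106984	0.8153343509051134	0.1510800930575996	0.9047356137042011	0.7872840333454021	0.0794735144271446	0.2832920829723363	0.3652933864024389	0.8155603457393328	0.3184693201382167	0.3075183850385227	0.1163292383795301
kidney_h006	0.4528052894207669	0.6629592274602342	0.0893636552110254	0.8944177917180206	0.8346486609345131	0.0934840611965815	0.3410768447979395	0.3336515079439906	0.7072296523935626	0.2875000217023225	0.3267752986971395	0.1096360876794460
kidney_d001	0.4263133297200473	0.8175535847594231	0.0658170888722247	0.7258092951796383	0.7908313902508516	0.0574535344371315	0.3372194681774335	0.3237452304039933	0.9888089865279578	0.2678865509736329	0.1289020247148310	0.1839927079488771
kidney_d002	0.2565291746173306	0.7415800792244340	0.1564984482414591	0.7627681230329918	0.7763300745261298	0.0837378647507534	0.2162088333422783	0.3070225658475084	0.9423539506301166	0.4095620456079374	0.2246252932096395	0.2223254065262309
kidney_d003	0.3328232717395493	0.7740030335144787	0.0737629248442675	0.7414825744523370	0.8056951779432802	0.0683302561099872	0.3250835798118411	0.3208088870205910	0.9659036116990856	0.2487741372031720	0.1969606550188861	0.1242337053391244
kidney_d004	0.3700137266521226	0.7919953830291869	0.0659360533932069	0.7992357250402979	0.7533867384085395	0.1237751598121892	0.2542155874595738	0.2833886431632178	0.9928356322331565	0.3171888829941270	0.1399557954694171	0.2030916676723280
kidney_d005	0.3810533740058412	0.7865663088580628	0.0405605545693455	0.6983242029276331	0.8452157751302293	0.0248185313869789	0.2959746817606035	0.3260967706651204	0.9665201846960905	0.3455542913821206	0.2431588094284646	0.1960578191952998
kidney_d006	0.4760336021727934	0.8076137280979069	0.0570054052780454	0.7774517300539372	0.7147719206732890	0.0489074566442991	0.4194488725158555	0.2819117434376128	0.9770935072740189	0.2639146308337230	0.2119341156895330	0.1407259716481748
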