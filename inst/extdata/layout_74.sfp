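Fpz  0.00000000000000000000000000  0.08749719949915413241825490 0.02842956348249517026238742
Fp1 -0.02703812160545376527820416  0.08321478174124757876128911 0.02842956348249517026238742
Fp2  0.02703812160545376527820416  0.08321478174124757876128911 0.02842956348249517026238742
AFz  0.00000000000000000000000000  0.07442956348249515907689045 0.05407624321090753055640832
AF1 -0.01371071443276091969543096  0.07640464963284154809031179 0.04937960939726040304753596
AF2  0.01371071443276091969543096  0.07640464963284154809031179 0.04937960939726040304753596
AF3 -0.02707486557191868606353502  0.07644846902439077218627261 0.04343481596702461478010093
AF4  0.02707486557191868606353502  0.07644846902439077218627261 0.04343481596702461478010093
AF5 -0.03975465014269065344709730  0.07455991404216526230452899 0.03639212840790154862569139
AF6  0.03975465014269065344709730  0.07455991404216526230452899 0.03639212840790154862569139
AF7 -0.05142956348249516640436241  0.07078672135503083495677856 0.02842956348249516332349351
AF8  0.05142956348249516640436241  0.07078672135503083495677856 0.02842956348249516332349351
Fz  0.00000000000000000000000000  0.05407624321090753055640832 0.07442956348249515907689045
F1 -0.02049929304098871071793120  0.05837912239358024335533770 0.06808565967496421622584535
F2  0.02049929304098871071793120  0.05837912239358024335533770 0.06808565967496421622584535
F3 -0.03983852348399527509847928  0.05937830538261349572204395 0.05788876312812573504684721
F4  0.03983852348399527509847928  0.05937830538261349572204395 0.05788876312812573504684721
F5 -0.05692327710381540201156625  0.05701724804198271545629950 0.04441592000039248921972046
F6  0.05692327710381540201156625  0.05701724804198271545629950 0.04441592000039248921972046
F7 -0.07078672135503083495677856  0.05142956348249516640436241 0.02842956348249516332349351
F8  0.07078672135503083495677856  0.05142956348249516640436241 0.02842956348249516332349351
FCz  0.00000000000000000000000000  0.02842956348249516332349351 0.08749719949915413241825490
FC1 -0.02612275143298130666846824  0.03226433128742916406350716 0.08210124715341231282916823
FC2  0.02612275143298130666846824  0.03226433128742916406350716 0.08210124715341231282916823
FC3 -0.05000414397810536842881035  0.03333078634868535949919988 0.06966092352528209519224589
FC4  0.05000414397810536842881035  0.03333078634868535949919988 0.06966092352528209519224589
FC5 -0.06959512964083969244200034  0.03153742572729580778689851 0.05124362115200305906048683
FC6  0.06959512964083969244200034  0.03153742572729580778689851 0.05124362115200305906048683
FT7 -0.08321478174124757876128911  0.02703812160545376874765111 0.02842956348249517026238742
FT8  0.08321478174124757876128911  0.02703812160545376874765111 0.02842956348249517026238742
Cz  0.00000000000000000000000000  0.00000000000000000000000000 0.09199999999999999844568777
C1 -0.02842956348249515985404656  0.00000000000000000174080870 0.08749719949915413241825490
C2  0.02842956348249515985404656  0.00000000000000000174080870 0.08749719949915413241825490
C3 -0.05407624321090753055640832  0.00000000000000000331121491 0.07442956348249515907689045
C4  0.05407624321090753055640832  0.00000000000000000331121491 0.07442956348249515907689045
C5 -0.07442956348249515907689045  0.00000000000000000455749633 0.05407624321090753055640832
C6  0.07442956348249515907689045  0.00000000000000000455749633 0.05407624321090753055640832
T7 -0.08749719949915413241825490  0.00000000000000000535765827 0.02842956348249517026238742
T8  0.08749719949915413241825490  0.00000000000000000535765827 0.02842956348249517026238742
CPz  0.00000000000000000348161739 -0.02842956348249516332349351 0.08749719949915413241825490
CP1 -0.02612275143298129626012738 -0.03226433128742915712461325 0.08210124715341231282916823
CP2  0.02612275143298131707680909 -0.03226433128742915712461325 0.08210124715341231282916823
CP3 -0.05000414397810537536770426 -0.03333078634868535256030597 0.06966092352528208131445808
CP4  0.05000414397810538924549206 -0.03333078634868535256030597 0.06966092352528208131445808
CP5 -0.06959512964083970631978815 -0.03153742572729580084800460 0.05124362115200307293827464
CP6  0.06959512964083970631978815 -0.03153742572729580084800460 0.05124362115200305906048683
TP7 -0.08321478174124757876128911 -0.02703812160545375486986330 0.02842956348249516332349351
TP8  0.08321478174124757876128911 -0.02703812160545375486986330 0.02842956348249516332349351
Pz  0.00000000000000000662242982 -0.05407624321090753055640832 0.07442956348249515907689045
P1 -0.02049929304098870377903729 -0.05837912239358024335533770 0.06808565967496423010363316
P2  0.02049929304098871765682510 -0.05837912239358024335533770 0.06808565967496421622584535
P3 -0.03983852348399528203737319 -0.05937830538261349572204395 0.05788876312812573504684721
P4  0.03983852348399528203737319 -0.05937830538261348878315005 0.05788876312812573504684721
P5 -0.05692327710381540201156625 -0.05701724804198270851740560 0.04441592000039248921972046
P6  0.05692327710381540201156625 -0.05701724804198270851740560 0.04441592000039248921972046
P7 -0.07078672135503083495677856 -0.05142956348249516640436241 0.02842956348249517026238742
P8  0.07078672135503083495677856 -0.05142956348249516640436241 0.02842956348249517026238742
POz  0.00000000000000000911499267 -0.07442956348249515907689045 0.05407624321090753055640832
PO1 -0.01371071443276091449126053 -0.07640464963284154809031179 0.04937960939726039610864206
PO2  0.01371071443276092663432486 -0.07640464963284154809031179 0.04937960939726039610864206
PO3 -0.02707486557191868953298197 -0.07644846902439077218627261 0.04343481596702462171899484
PO4  0.02707486557191869994132283 -0.07644846902439077218627261 0.04343481596702462171899484
PO5 -0.03975465014269066732488511 -0.07455991404216524842674119 0.03639212840790155556458529
PO6  0.03975465014269066732488511 -0.07455991404216524842674119 0.03639212840790155556458529
PO7 -0.05142956348249517334325631 -0.07078672135503082107899075 0.02842956348249516332349351
PO8  0.05142956348249517334325631 -0.07078672135503082107899075 0.02842956348249516332349351
Oz  0.00000000000000001071531653 -0.08749719949915413241825490 0.02842956348249517026238742
O1 -0.02703812160545377568654501 -0.08321478174124757876128911 0.02842956348249517026238742
O2  0.02703812160545377568654501 -0.08321478174124757876128911 0.02842956348249517026238742
Iz  0.00000000000000001126675055 -0.09199999999999999844568777 0.00000000000000000563337528
T9 -0.09199999999999999844568777  0.00000000000000000563337528 0.00000000000000000563337528
T10  0.09199999999999999844568777  0.00000000000000000563337528 0.00000000000000000563337528
TP9 -0.08749719949915413241825490 -0.02842956348249515638459961 0.00000000000000000563337528
TP10  0.08749719949915413241825490 -0.02842956348249515638459961 0.00000000000000000563337528
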