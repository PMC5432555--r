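Fp1 -0.02703812160545376527820416  0.08321478174124757876128911 0.02842956348249517026238742
Fp2  0.02703812160545376527820416  0.08321478174124757876128911 0.02842956348249517026238742
F7 -0.07078672135503083495677856  0.05142956348249516640436241 0.02842956348249516332349351
F3 -0.03983852348399527509847928  0.05937830538261349572204395 0.05788876312812573504684721
Fz  0.00000000000000000000000000  0.05407624321090753055640832 0.07442956348249515907689045
F4  0.03983852348399527509847928  0.05937830538261349572204395 0.05788876312812573504684721
F8  0.07078672135503083495677856  0.05142956348249516640436241 0.02842956348249516332349351
T7 -0.08749719949915413241825490  0.00000000000000000535765827 0.02842956348249517026238742
C3 -0.05407624321090753055640832  0.00000000000000000331121491 0.07442956348249515907689045
Cz  0.00000000000000000000000000  0.00000000000000000000000000 0.09199999999999999844568777
C4  0.05407624321090753055640832  0.00000000000000000331121491 0.07442956348249515907689045
T8  0.08749719949915413241825490  0.00000000000000000535765827 0.02842956348249517026238742
P7 -0.07078672135503083495677856 -0.05142956348249516640436241 0.02842956348249517026238742
P3 -0.03983852348399528203737319 -0.05937830538261349572204395 0.05788876312812573504684721
Pz  0.00000000000000000662242982 -0.05407624321090753055640832 0.07442956348249515907689045
P4  0.03983852348399528203737319 -0.05937830538261348878315005 0.05788876312812573504684721
P8  0.07078672135503083495677856 -0.05142956348249516640436241 0.02842956348249517026238742
O1 -0.02703812160545377568654501 -0.08321478174124757876128911 0.02842956348249517026238742
O2  0.02703812160545377568654501 -0.08321478174124757876128911 0.02842956348249517026238742
TP9 -0.08749719949915413241825490 -0.02842956348249515638459961 0.00000000000000000563337528
TP10  0.08749719949915413241825490 -0.02842956348249515638459961 0.00000000000000000563337528
AFz  0.00000000000000000000000000  0.07442956348249515907689045 0.05407624321090753055640832
FC5 -0.06959512964083969244200034  0.03153742572729580778689851 0.05124362115200305906048683
FC1 -0.02612275143298130666846824  0.03226433128742916406350716 0.08210124715341231282916823
FC2  0.02612275143298130666846824  0.03226433128742916406350716 0.08210124715341231282916823
FC6  0.06959512964083969244200034  0.03153742572729580778689851 0.05124362115200305906048683
CP5 -0.06959512964083970631978815 -0.03153742572729580084800460 0.05124362115200307293827464
CP1 -0.02612275143298129626012738 -0.03226433128742915712461325 0.08210124715341231282916823
CP2  0.02612275143298131707680909 -0.03226433128742915712461325 0.08210124715341231282916823
CP6  0.06959512964083970631978815 -0.03153742572729580084800460 0.05124362115200305906048683
PO7 -0.05142956348249517334325631 -0.07078672135503082107899075 0.02842956348249516332349351
POz  0.00000000000000000911499267 -0.07442956348249515907689045 0.05407624321090753055640832
PO8  0.05142956348249517334325631 -0.07078672135503082107899075 0.02842956348249516332349351
Oz  0.00000000000000001071531653 -0.08749719949915413241825490 0.02842956348249517026238742
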