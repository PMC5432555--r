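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
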