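label	x	y	z
Fp1	76.8832222609353	24.9808732224301	26.2664445218705
AF7	65.4007751649741	47.5164445218705	26.2664445218705
AF3	70.6317376855785	25.0148214523162	40.1299930130119
F1	53.9372326462426	18.9395642226526	62.9052290475213
F3	54.860390842632	36.8073314797783	53.4841833248988
F5	52.6789791692232	52.5921581937425	41.0364478264496
F7	47.5164445218705	65.4007751649741	26.2664445218705
FT7	24.9808732224301	76.8832222609353	26.2664445218705
FC5	29.1378389871755	64.2998480377323	47.3446499773941
FC3	30.7947482569376	46.1994808493365	64.3606358657497
FC1	29.8094365155595	24.1351507804719	75.85441313087
C1	1.60835586043451e-15	26.2664445218705	80.839803885088
C3	3.05927464317549e-15	49.9617464448602	68.7664445218705
C5	4.21073030862264e-15	68.7664445218705	49.9617464448602
T7	4.95001035357864e-15	80.839803885088	26.2664445218705
TP7	-24.9808732224301	76.8832222609353	26.2664445218705
CP5	-29.1378389871755	64.2998480377323	47.3446499773941
CP3	-30.7947482569375	46.1994808493365	64.3606358657497
CP1	-29.8094365155595	24.1351507804719	75.85441313087
P1	-53.9372326462426	18.9395642226526	62.9052290475213
P3	-54.860390842632	36.8073314797783	53.4841833248988
P5	-52.6789791692232	52.5921581937425	41.0364478264496
P7	-47.5164445218705	65.4007751649741	26.2664445218705
P9	-49.9617464448602	68.7664445218705	5.20474889637625e-15
PO7	-65.4007751649741	47.5164445218705	26.2664445218705
PO3	-70.6317376855785	25.0148214523162	40.1299930130119
O1	-76.8832222609353	24.9808732224301	26.2664445218705
Iz	-85	1.04094977927525e-14	5.20474889637625e-15
Oz	-80.839803885088	9.90002070715728e-15	26.2664445218705
POz	-68.7664445218705	8.42146061724528e-15	49.9617464448602
Pz	-49.9617464448602	6.11854928635097e-15	68.7664445218705
CPz	-26.2664445218705	3.21671172086903e-15	80.839803885088
Fpz	80.839803885088	0	26.2664445218705
Fp2	76.8832222609353	-24.9808732224301	26.2664445218705
AF8	65.4007751649741	-47.5164445218705	26.2664445218705
AF4	70.6317376855785	-25.0148214523162	40.1299930130119
AFz	68.7664445218705	0	49.9617464448602
Fz	49.9617464448602	0	68.7664445218705
F2	53.9372326462426	-18.9395642226526	62.9052290475213
F4	54.860390842632	-36.8073314797783	53.4841833248988
F6	52.6789791692232	-52.5921581937425	41.0364478264496
F8	47.5164445218705	-65.4007751649741	26.2664445218705
FT8	24.9808732224301	-76.8832222609353	26.2664445218705
FC6	29.1378389871755	-64.2998480377323	47.3446499773941
FC4	30.7947482569376	-46.1994808493365	64.3606358657497
FC2	29.8094365155595	-24.1351507804719	75.85441313087
FCz	26.2664445218705	0	80.839803885088
Cz	0	0	85
C2	1.60835586043451e-15	-26.2664445218705	80.839803885088
C4	3.05927464317549e-15	-49.9617464448602	68.7664445218705
C6	4.21073030862264e-15	-68.7664445218705	49.9617464448602
T8	4.95001035357864e-15	-80.839803885088	26.2664445218705
TP8	-24.9808732224301	-76.8832222609353	26.2664445218705
CP6	-29.1378389871755	-64.2998480377323	47.3446499773941
CP4	-30.7947482569376	-46.1994808493365	64.3606358657497
CP2	-29.8094365155596	-24.1351507804719	75.8544131308701
P2	-53.9372326462426	-18.9395642226526	62.9052290475213
P4	-54.860390842632	-36.8073314797782	53.4841833248988
P6	-52.6789791692232	-52.5921581937425	41.0364478264496
P8	-47.5164445218705	-65.4007751649741	26.2664445218705
P10	-49.9617464448602	-68.7664445218705	5.20474889637625e-15
PO8	-65.4007751649741	-47.5164445218705	26.2664445218705
PO4	-70.6317376855784	-25.0148214523162	40.1299930130119
O2	-76.8832222609353	-24.9808732224301	26.2664445218705
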