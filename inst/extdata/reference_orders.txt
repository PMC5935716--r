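# Reference mitochondrial gene orders packaged with mitorearr.
# PanGO: ancestral insect arrangement; ant1GO: plesiomorphic hymenopteran
# ground pattern (figure-transcribed); ChalcidoidGO: presumed chalcidoid
# ancestor; TrichogrammaGO: from the printed annotation table.
# Other chalcidoid orders are best-effort figure transcriptions
# (confidence: figure).
PanGO: trnI -trnQ trnM nad2 trnW -trnC -trnY cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
ant1GO: trnI -trnQ trnM nad2 trnW -trnC -trnY cox1 trnL2 cox2 trnK trnD atp8 atp6 cox3 trnG nad3 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
ChalcidoidGO: trnI -trnQ trnM nad2 trnW -trnC -trnY -nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
TrichogrammaGO: -trnW -nad2 -trnQ -trnY -cox1 trnE -trnF -trnI -trnS1 -trnN -trnC -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnA -trnG -rrnS -trnV -trnR -nad3 -trnM CR
Megaphragma: trnM trnI -trnQ nad2 -trnC trnW -trnY -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 -nad3 -trnG trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
Philotrypesis: trnI trnM -trnQ nad2 trnW -trnY -trnC -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 trnS1 trnG nad3 trnA trnR trnN trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob -nad1 trnS2 -trnL1 -rrnL -trnV -rrnS CR
Ceratosolen: trnM trnI -trnQ nad2 -trnY trnW -trnC -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 nad3 trnG trnA trnR trnN trnS1 trnE -trnF -nad5 -trnH -nad4 -nad4l trnT -trnP nad6 cob -nad1 trnS2 -trnL1 -rrnL -trnV -rrnS CR
Nasonia_vitripennis: trnI -trnQ trnM nad2 trnW -trnC -trnY -nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 trnA trnR trnN trnS1 trnE -trnF -nad5 trnT -trnH -nad4 -nad4l -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
Nasonia_giraulti: trnI -trnQ trnM nad2 trnW -trnC -trnY -nad3 -trnG -cox3 -atp6 -atp8 -trnD trnK -cox2 -trnL2 -cox1 trnA trnR trnN trnS1 trnE -trnF -nad5 trnT -trnH -nad4 -nad4l -trnP nad6 cob trnS2 -nad1 -trnL1 -rrnL -trnV -rrnS CR
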