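participant_id,item_id,item_class,judged_known
adult_p001,fam1,familiar,1
adult_p001,fam2,familiar,1
adult_p001,fam3,familiar,1
adult_p001,fam4,familiar,0
adult_p001,fam5,familiar,1
adult_p001,unfam1,unfamiliar,0
adult_p001,unfam2,unfamiliar,0
adult_p001,unfam3,unfamiliar,0
adult_p001,unfam4,unfamiliar,0
adult_p002,fam1,familiar,1
adult_p002,fam2,familiar,1
adult_p002,fam3,familiar,1
adult_p002,fam4,familiar,1
adult_p002,fam5,familiar,1
adult_p002,unfam1,unfamiliar,0
adult_p002,unfam2,unfamiliar,0
adult_p002,unfam3,unfamiliar,0
adult_p002,unfam4,unfamiliar,0
adult_p003,fam1,familiar,1
adult_p003,fam2,familiar,1
adult_p003,fam3,familiar,1
adult_p003,fam4,familiar,1
adult_p003,fam5,familiar,1
adult_p003,unfam1,unfamiliar,0
adult_p003,unfam2,unfamiliar,1
adult_p003,unfam3,unfamiliar,0
adult_p003,unfam4,unfamiliar,0
5yo_p001,fam1,familiar,1
5yo_p001,fam2,familiar,1
5yo_p001,fam3,familiar,1
5yo_p001,fam4,familiar,1
5yo_p001,fam5,familiar,1
5yo_p001,unfam1,unfamiliar,0
5yo_p001,unfam2,unfamiliar,0
5yo_p001,unfam3,unfamiliar,0
5yo_p001,unfam4,unfamiliar,0
5yo_p002,fam1,familiar,1
5yo_p002,fam2,familiar,1
5yo_p002,fam3,familiar,1
5yo_p002,fam4,familiar,1
5yo_p002,fam5,familiar,1
5yo_p002,unfam1,unfamiliar,0
5yo_p002,unfam2,unfamiliar,1
5yo_p002,unfam3,unfamiliar,0
5yo_p002,unfam4,unfamiliar,0
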