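participant_id,age_group,object_id,learned,knowledge_judgement,times_sampled,test_correct,confidence_rating
adult_p001,adult,obj02,1,1,0,1,1
adult_p001,adult,obj06,1,1,1,0,1
adult_p001,adult,obj11,0,0,1,0,0
adult_p001,adult,obj14,1,0,0,1,1
adult_p001,adult,obj12,0,0,0,0,0
adult_p001,adult,obj08,1,0,1,1,1
adult_p002,adult,obj06,1,1,1,1,1
adult_p002,adult,obj09,1,1,1,1,0
adult_p002,adult,obj10,1,1,0,1,1
adult_p002,adult,obj04,1,1,1,1,0
adult_p002,adult,obj14,0,0,0,0,1
adult_p002,adult,obj11,1,1,0,1,1
adult_p003,adult,obj11,0,0,1,0,0
adult_p003,adult,obj01,1,1,0,1,1
adult_p003,adult,obj12,0,0,1,0,1
adult_p003,adult,obj05,1,1,0,1,1
adult_p003,adult,obj14,1,1,1,1,1
adult_p003,adult,obj02,1,1,0,1,1
5yo_p001,5yo,obj03,1,1,1,1,1
5yo_p001,5yo,obj10,1,1,0,1,1
5yo_p001,5yo,obj13,0,0,1,0,1
5yo_p001,5yo,obj12,0,1,1,1,1
5yo_p001,5yo,obj07,1,1,0,1,1
5yo_p001,5yo,obj01,1,1,0,1,1
5yo_p002,5yo,obj09,1,1,1,1,1
5yo_p002,5yo,obj12,1,1,1,1,1
5yo_p002,5yo,obj04,1,0,0,1,1
5yo_p002,5yo,obj11,0,1,0,0,1
5yo_p002,5yo,obj06,0,0,1,0,1
5yo_p002,5yo,obj10,0,0,0,0,0
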