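item_id,format,reverse_coded,label_key,in_final_scale
FTS01,ladder10,TRUE,love_in_family,TRUE
FTS02,ladder10,TRUE,understanding,TRUE
FTS03,ladder10,TRUE,organized,TRUE
FTS04,ladder10,TRUE,members_friendly,TRUE
FTS05,ladder10,TRUE,show_concern,TRUE
FTS06,ladder10,TRUE,roles_satisfaction,TRUE
FTS07,ladder10,TRUE,together_unified,TRUE
FTS08,ladder10,TRUE,relates_well,TRUE
FTS09,ladder10,FALSE,go_own_way,TRUE
FTS10,ladder10,TRUE,work_together,TRUE
FTS11,ladder10,TRUE,children_equal,TRUE
FTS12,ladder10,TRUE,age_appropriate_work,TRUE
FTS13,ladder10,FALSE,unequal_punishment,TRUE
FTS14,ladder10,TRUE,greet_happily,TRUE
FTS15,ladder10,TRUE,tasks_together,TRUE
FTS16,ladder10,TRUE,sit_and_talk,TRUE
FTS17,ladder10,TRUE,sleep_at_home,TRUE
FTS18,ladder10,TRUE,sit_and_laugh,TRUE
FTS19,ladder10,TRUE,listen_to_each_other,TRUE
FTS20,ladder10,FALSE,have_quarrels,TRUE
FTS21,ladder10,FALSE,spouse_quarrel_children,TRUE
FTS22,ladder10,TRUE,say_sorry,TRUE
FTS23,ladder10,FALSE,blame_each_other,TRUE
FTS24,ladder10,FALSE,misunderstanding,TRUE
FTS25,ladder10,FALSE,provider_confusion,TRUE
FTS26,ladder10,FALSE,adults_idle,TRUE
FTS27,comm4,FALSE,problems_money,TRUE
FTS28,comm4,FALSE,problems_school,TRUE
FTS29,comm4,FALSE,problems_extended_family,TRUE
FTS30,comm4,FALSE,biggest_problem,TRUE
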