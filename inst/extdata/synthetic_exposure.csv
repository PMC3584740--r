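"population_id","sex","population","pcc_recorded","pcc_unrecorded","pcc_tourist","p_lifetime_abstainer","p_former","p_current"
"pop01","female",13940832,1.63351739937168,0.25059971097187,0.11433310477455,0.255831473094877,0.125550899449736,0.618617627455387
"pop01","male",24899861,2.64016083955753,1.15381494172525,0.456662540414482,0.308493621798698,0.0635813154280186,0.627925062773284
"pop02","female",2279356,2.51526497236279,0.340186840934448,0.251838575735785,0.219162164982408,0.10492248066701,0.675915354350582
"pop02","male",4573463,8.3385755471274,5.39998781413875,0.134795606376651,0.0882150952378288,0.107864672932774,0.803920231829397
"pop03","female",18190713,4.04329059557626,1.23907505450215,0.256492659758583,0.0974326148955152,0.102778260726482,0.799789124378003
"pop03","male",8918700,13.5002227976266,1.55426907305797,0.238691432705892,0.052309340897482,0.131827505053952,0.815863154048566
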