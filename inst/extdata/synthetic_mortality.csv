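"population_id","sex","cause","deaths"
"pop01","male","oral cavity and pharynx cancer",16658
"pop02","male","oral cavity and pharynx cancer",1784
"pop03","male","oral cavity and pharynx cancer",17960
"pop01","female","oral cavity and pharynx cancer",1555
"pop02","female","oral cavity and pharynx cancer",13655
"pop03","female","oral cavity and pharynx cancer",13658
"pop01","male","esophageal cancer",13946
"pop02","male","esophageal cancer",14049
"pop03","male","esophageal cancer",6845
"pop01","female","esophageal cancer",7559
"pop02","female","esophageal cancer",10577
"pop03","female","esophageal cancer",11754
"pop01","male","colorectal cancer",7778
"pop02","male","colorectal cancer",184
"pop03","male","colorectal cancer",12004
"pop01","female","colorectal cancer",16547
"pop02","female","colorectal cancer",16638
"pop03","female","colorectal cancer",1121
"pop01","male","liver cancer",1637
"pop02","male","liver cancer",19647
"pop03","male","liver cancer",4195
"pop01","female","liver cancer",18474
"pop02","female","liver cancer",10779
"pop03","female","liver cancer",4018
"pop01","male","breast cancer",0
"pop02","male","breast cancer",0
"pop03","male","breast cancer",0
"pop01","female","breast cancer",8288
"pop02","female","breast cancer",10565
"pop03","female","breast cancer",1994
"pop01","male","epilepsy",543
"pop02","male","epilepsy",19622
"pop03","male","epilepsy",16921
"pop01","female","epilepsy",10014
"pop02","female","epilepsy",14170
"pop03","female","epilepsy",14308
"pop01","male","lower respiratory infections",1577
"pop02","male","lower respiratory infections",9504
"pop03","male","lower respiratory infections",5863
"pop01","female","lower respiratory infections",11946
"pop02","female","lower respiratory infections",15155
"pop03","female","lower respiratory infections",4668
"pop01","male","stroke",16535
"pop02","male","stroke",11842
"pop03","male","stroke",7938
"pop01","female","stroke",6927
"pop02","female","stroke",11892
"pop03","female","stroke",13766
"pop01","male","hypertension",5573
"pop02","male","hypertension",13911
"pop03","male","hypertension",1153
"pop01","female","hypertension",5852
"pop02","female","hypertension",9998
"pop03","female","hypertension",1330
"pop01","male","liver cirrhosis",9762
"pop02","male","liver cirrhosis",2874
"pop03","male","liver cirrhosis",14467
"pop01","female","liver cirrhosis",17812
"pop02","female","liver cirrhosis",11870
"pop03","female","liver cirrhosis",5168
"pop01","male","diabetes",5455
"pop02","male","diabetes",11593
"pop03","male","diabetes",4241
"pop01","female","diabetes",4440
"pop02","female","diabetes",6900
"pop03","female","diabetes",17944
"pop01","male","tuberculosis",16947
"pop02","male","tuberculosis",2260
"pop03","male","tuberculosis",9443
"pop01","female","tuberculosis",6928
"pop02","female","tuberculosis",150
"pop03","female","tuberculosis",19361
"pop01","male","ischemic heart disease",12658
"pop02","male","ischemic heart disease",3412
"pop03","male","ischemic heart disease",18292
"pop01","female","ischemic heart disease",15930
"pop02","female","ischemic heart disease",2796
"pop03","female","ischemic heart disease",7313
"pop01","male","motor vehicle accidents",13110
"pop02","male","motor vehicle accidents",10641
"pop03","male","motor vehicle accidents",5414
"pop01","female","motor vehicle accidents",17644
"pop02","female","motor vehicle accidents",4755
"pop03","female","motor vehicle accidents",10824
"pop01","male","suicide",3701
"pop02","male","suicide",12303
"pop03","male","suicide",4833
"pop01","female","suicide",6338
"pop02","female","suicide",8841
"pop03","female","suicide",7981
"pop01","male","other injuries",3389
"pop02","male","other injuries",16204
"pop03","male","other injuries",4455
"pop01","female","other injuries",10411
"pop02","female","other injuries",15586
"pop03","female","other injuries",6885
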