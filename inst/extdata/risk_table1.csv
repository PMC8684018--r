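factor,sex_stratum,site,rr,increment,unit,direction,ci_includes_null
red_meat,men,colorectal,1.28,100,g_per_day,detrimental,TRUE
red_meat,women,colorectal,1.02,100,g_per_day,detrimental,TRUE
red_meat,persons,colorectal,1.12,100,g_per_day,detrimental,TRUE
processed_meat,men,colorectal,1.11,50,g_per_day,detrimental,TRUE
processed_meat,women,colorectal,1.18,50,g_per_day,detrimental,TRUE
processed_meat,persons,colorectal,1.16,50,g_per_day,detrimental,FALSE
fiber,men,colorectal,0.89,10,g_per_day,protective,FALSE
fiber,women,colorectal,0.91,10,g_per_day,protective,FALSE
fiber,persons,colorectal,0.93,10,g_per_day,protective,TRUE
calcium,men,colorectal,0.93,200,mg_per_day,protective,FALSE
calcium,women,colorectal,0.93,200,mg_per_day,protective,FALSE
calcium,persons,colorectal,0.94,200,mg_per_day,protective,FALSE
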