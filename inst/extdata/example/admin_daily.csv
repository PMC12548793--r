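site,item_id,count_per_day
site01,mat008,2
site01,mat009,2
site01,mat010,1
site01,mat011,3
site01,mat012,3
site02,mat008,3
site02,mat009,1
site02,mat010,1
site02,mat011,2
site02,mat012,1
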