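product_id,item_id,site,count_per_dose
prod001,mat004,site01,2
prod001,mat007,site01,2
prod001,prod001-box,site01,0.1
prod001,prod001-container,site01,1
prod001,mat004,site02,2
prod001,mat007,site02,2
prod001,prod001-box,site02,0.1
prod001,prod001-container,site02,1
prod002,mat001,site01,1
prod002,mat002,site01,2
prod002,mat004,site01,1
prod002,mat007,site01,2
prod002,prod002-box,site01,0.0833333333333333
prod002,prod002-container,site01,1
prod002,mat001,site02,1
prod002,mat002,site02,2
prod002,mat007,site02,2
prod002,prod002-box,site02,0.0833333333333333
prod002,prod002-container,site02,1
prod003,mat004,site01,2
prod003,mat005,site01,1
prod003,prod003-box,site01,0.0416666666666667
prod003,prod003-container,site01,1
prod003,mat004,site02,2
prod003,mat005,site02,1
prod003,prod003-box,site02,0.0416666666666667
prod003,prod003-container,site02,1
prod004,mat001,site01,2
prod004,mat005,site01,2
prod004,mat006,site01,2
prod004,mat007,site01,1
prod004,prod004-box,site01,0.0416666666666667
prod004,prod004-container,site01,1
prod004,mat001,site02,2
prod004,mat005,site02,2
prod004,mat006,site02,2
prod004,mat007,site02,1
prod004,prod004-box,site02,0.0416666666666667
prod004,prod004-container,site02,1
prod005,mat001,site01,1
prod005,mat007,site01,1
prod005,prod005-box,site01,0.166666666666667
prod005,prod005-container,site01,1
prod005,mat001,site02,1
prod005,mat007,site02,1
prod005,prod005-box,site02,0.166666666666667
prod005,prod005-container,site02,1
prod006,mat002,site01,2
prod006,mat003,site01,2
prod006,prod006-box,site01,0.166666666666667
prod006,prod006-container,site01,1
prod006,mat002,site02,2
prod006,mat003,site02,2
prod006,mat004,site02,1
prod006,prod006-box,site02,0.166666666666667
prod006,prod006-container,site02,1
prod007,mat001,site01,1
prod007,mat002,site01,1
prod007,mat004,site01,2
prod007,mat005,site01,2
prod007,mat006,site01,2
prod007,prod007-box,site01,0.1
prod007,prod007-container,site01,1
prod007,mat002,site02,1
prod007,mat004,site02,2
prod007,mat005,site02,2
prod007,mat006,site02,2
prod007,prod007-box,site02,0.1
prod007,prod007-container,site02,1
prod008,mat001,site01,1
prod008,mat004,site01,1
prod008,mat005,site01,1
prod008,mat006,site01,2
prod008,mat007,site01,1
prod008,prod008-box,site01,0.0833333333333333
prod008,prod008-container,site01,1
prod008,mat001,site02,1
prod008,mat003,site02,1
prod008,mat005,site02,1
prod008,mat006,site02,2
prod008,mat007,site02,1
prod008,prod008-box,site02,0.0833333333333333
prod008,prod008-container,site02,1
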