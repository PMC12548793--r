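product_id,agent,dose_label,formulation,doses_per_day
prod001,vancomycin,600 mg/100 mL,local_compound,4
prod002,cefazolin,750 mg/250 mL,minibag_plus,6
prod003,ceftriaxone,600 mg/250 mL,local_compound,3
prod004,cefepime,2 g/50 mL,minibag_plus,1
prod005,vancomycin,1 g/250 mL,nonfrozen_premix,6
prod006,cefazolin,600 mg/250 mL,local_compound,6
prod007,ceftriaxone,600 mg/50 mL,local_compound,2
prod008,cefepime,2 g/250 mL,nonfrozen_premix,4
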