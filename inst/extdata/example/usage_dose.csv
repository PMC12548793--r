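agent,dose_label,n_doses
vancomycin,600 mg/100 mL,491
cefazolin,750 mg/250 mL,3914
ceftriaxone,600 mg/250 mL,3726
cefepime,2 g/50 mL,4564
vancomycin,1 g/250 mL,4675
cefazolin,600 mg/250 mL,3333
ceftriaxone,600 mg/50 mL,3046
cefepime,2 g/250 mL,3348
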