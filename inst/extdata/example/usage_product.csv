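product_id,n_doses
prod001,4754
prod002,614
prod003,2019
prod004,4608
prod005,3337
prod006,4302
prod007,2808
prod008,4980
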