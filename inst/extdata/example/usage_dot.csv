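agent,iv_dot
vancomycin,459
cefazolin,2931
ceftriaxone,1915
cefepime,83
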