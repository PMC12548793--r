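alias,canonical
vancomycin hcl,vancomycin
vancomycin hydrochloride,vancomycin
vancocin,vancomycin
zosyn,piperacillin-tazobactam
pip-tazo,piperacillin-tazobactam
piptazo,piperacillin-tazobactam
unasyn,ampicillin-sulbactam
bactrim,trimethoprim-sulfamethoxazole
septra,trimethoprim-sulfamethoxazole
cotrimoxazole,trimethoprim-sulfamethoxazole
co-trimoxazole,trimethoprim-sulfamethoxazole
sulfamethoxazole-trimethoprim,trimethoprim-sulfamethoxazole
penicillin g potassium,penicillin g
penicillin g sodium,penicillin g
benzylpenicillin,penicillin g
liposomal amphotericin b,amphotericin b
amphotericin b liposomal,amphotericin b
ambisome,amphotericin b
imipenem,imipenem-cilastatin
primaxin,imipenem-cilastatin
zithromax,azithromycin
flagyl,metronidazole
zyvox,linezolid
cubicin,daptomycin
maxipime,cefepime
ancef,cefazolin
rocephin,ceftriaxone
zerbaxa,ceftolozane-tazobactam
avycaz,ceftazidime-avibactam
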