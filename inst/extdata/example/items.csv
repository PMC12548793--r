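item_id,name,role,material,site,mass_g
mat001,sterile water vial,preparation,hdpe,site01,2.99
mat001,sterile water vial,preparation,hdpe,site02,2.9
mat002,blunt fill needle,preparation,mixed plastics,site01,1.23
mat002,blunt fill needle,preparation,mixed plastics,site02,1.36
mat003,dispensing pin,preparation,pet,site01,16.92
mat003,dispensing pin,preparation,pet,site02,16.76
mat004,dispensing pin,preparation,glass,site01,1.96
mat004,dispensing pin,preparation,glass,site02,1.63
mat005,compounding bag overwrap,preparation,mixed paper (general),site01,2.24
mat005,compounding bag overwrap,preparation,mixed paper (general),site02,2.3
mat006,alcohol prep pad,preparation,mixed plastics,site01,5.5
mat006,alcohol prep pad,preparation,mixed plastics,site02,6.41
mat007,filter needle,preparation,ldpe,site01,1.73
mat007,filter needle,preparation,ldpe,site02,1.65
mat008,tubing label,administration,glass,site01,0.63
mat008,tubing label,administration,glass,site02,0.54
mat009,IV end cap,administration,ldpe,site01,9.37
mat009,IV end cap,administration,ldpe,site02,9.52
mat010,saline flush syringe,administration,mixed paper (general),site01,1.04
mat010,saline flush syringe,administration,mixed paper (general),site02,1.03
mat011,alcohol swab,administration,hdpe,site01,4.66
mat011,alcohol swab,administration,hdpe,site02,5.3
mat012,saline flush syringe,administration,corrugated containers,site01,0.91
mat012,saline flush syringe,administration,corrugated containers,site02,0.91
prod001-box,vial paperboard box,drug_packaging,mixed paper (general),site01,15.6
prod001-box,vial paperboard box,drug_packaging,mixed paper (general),site02,16.4
prod001-container,drug powder vial (empty),drug_container,glass,site01,36.93
prod001-container,drug powder vial (empty),drug_container,glass,site02,37.53
prod002-box,vial paperboard box,drug_packaging,mixed paper (general),site01,37.27
prod002-box,vial paperboard box,drug_packaging,mixed paper (general),site02,36.76
prod002-container,drug powder vial (empty),drug_container,glass,site01,17.67
prod002-container,drug powder vial (empty),drug_container,glass,site02,18.13
prod003-box,vial paperboard box,drug_packaging,mixed paper (general),site01,37.39
prod003-box,vial paperboard box,drug_packaging,mixed paper (general),site02,35.71
prod003-container,drug powder vial (empty),drug_container,glass,site01,54.92
prod003-container,drug powder vial (empty),drug_container,glass,site02,48.51
prod004-box,vial paperboard box,drug_packaging,mixed paper (general),site01,29.13
prod004-box,vial paperboard box,drug_packaging,mixed paper (general),site02,30.72
prod004-container,drug powder vial (empty),drug_container,glass,site01,50.23
prod004-container,drug powder vial (empty),drug_container,glass,site02,47.87
prod005-box,premix corrugated box,drug_packaging,corrugated containers,site01,11.23
prod005-box,premix corrugated box,drug_packaging,corrugated containers,site02,10.6
prod005-container,premix bag (empty and dry),drug_container,mixed plastics,site01,53.23
prod005-container,premix bag (empty and dry),drug_container,mixed plastics,site02,51.98
prod006-box,vial paperboard box,drug_packaging,mixed paper (general),site01,11.71
prod006-box,vial paperboard box,drug_packaging,mixed paper (general),site02,12.34
prod006-container,drug powder vial (empty),drug_container,glass,site01,10.64
prod006-container,drug powder vial (empty),drug_container,glass,site02,10.06
prod007-box,vial paperboard box,drug_packaging,mixed paper (general),site01,64.15
prod007-box,vial paperboard box,drug_packaging,mixed paper (general),site02,68.89
prod007-container,drug powder vial (empty),drug_container,glass,site01,45.29
prod007-container,drug powder vial (empty),drug_container,glass,site02,49.91
prod008-box,premix corrugated box,drug_packaging,corrugated containers,site01,49.42
prod008-box,premix corrugated box,drug_packaging,corrugated containers,site02,49.93
prod008-container,premix bag (empty and dry),drug_container,mixed plastics,site01,28.13
prod008-container,premix bag (empty and dry),drug_container,mixed plastics,site02,30.42
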