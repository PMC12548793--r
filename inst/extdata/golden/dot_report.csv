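# abxcarbon report
# mode: dot
# scenario: default=landfilled
# provenance: EPA GHG Emission Factors Hub waste table (transcribed 2025)
key,quantity,co2e_short_tons,co2e_metric_tons,waste_mass_short_tons,waste_mass_g,miles driven by average passenger vehicle,gallons of gasoline consumed,smartphones charged,tree seedlings grown for 10 years,co2e_short_tons (2dp),co2e_metric_tons (2dp),waste_mass_short_tons (2dp),waste_mass_g (2dp),miles driven by average passenger vehicle (2dp),gallons of gasoline consumed (2dp),smartphones charged (2dp),tree seedlings grown for 10 years (2dp)
cefazolin,2931,0.0875197693596832,0.0793965992114242,0.878446493434182,796913.25375,202.026970003624,8.93401588966177,9658.95367535574,1.32327665352374,0.09,0.08,0.88,796913.25,202.03,8.93,9658.95,1.32
cefepime,83,0.00241297511019634,0.00218901419796994,0.0174925629214545,15868.9861458333,5.57001068185735,0.246316439515015,266.303430409968,0.0364835699661656,0.00,0.00,0.02,15868.99,5.57,0.25,266.30,0.04
ceftriaxone,1915,0.057626138426027,0.0522775534052193,0.415095422708499,376568.233125,133.021764389871,5.88247478397877,6359.79968433325,0.871292556753655,0.06,0.05,0.42,376568.23,133.02,5.88,6359.80,0.87
vancomycin,459,0.010328549400731,0.00936990240267931,0.15164280375792,137568.0375,23.8419908465122,1.05433806714069,1139.89080324566,0.156165040044655,0.01,0.01,0.15,137568.04,23.84,1.05,1139.89,0.16
TOTAL,5388,0.157887432296638,0.143233069217293,1.46267728282206,1326918.51052083,364.460735921864,16.1171451802962,17424.9475933446,2.38721782028821,0.16,0.14,1.46,1326918.51,364.46,16.12,17424.95,2.39
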