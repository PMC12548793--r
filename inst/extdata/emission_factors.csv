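material,disposal_method,mtco2e_per_short_ton,source
aluminum cans,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
aluminum cans,recycled,0.06,EPA GHG Emission Factors Hub waste table (transcribed 2025)
aluminum cans,combusted,0.01,EPA GHG Emission Factors Hub waste table (transcribed 2025)
corrugated containers,landfilled,1.13,EPA GHG Emission Factors Hub waste table (transcribed 2025)
corrugated containers,recycled,0.09,EPA GHG Emission Factors Hub waste table (transcribed 2025)
corrugated containers,combusted,0.11,EPA GHG Emission Factors Hub waste table (transcribed 2025)
glass,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
glass,recycled,0.05,EPA GHG Emission Factors Hub waste table (transcribed 2025)
glass,combusted,0.01,EPA GHG Emission Factors Hub waste table (transcribed 2025)
hdpe,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
hdpe,recycled,0.09,EPA GHG Emission Factors Hub waste table (transcribed 2025)
hdpe,combusted,1.34,EPA GHG Emission Factors Hub waste table (transcribed 2025)
ldpe,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
ldpe,combusted,1.34,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed,landfilled,0.58,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed,combusted,0.43,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed paper (general),landfilled,1.07,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed paper (general),recycled,0.07,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed paper (general),combusted,0.11,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed plastics,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed plastics,recycled,0.09,EPA GHG Emission Factors Hub waste table (transcribed 2025)
mixed plastics,combusted,1.26,EPA GHG Emission Factors Hub waste table (transcribed 2025)
newspaper,landfilled,0.85,EPA GHG Emission Factors Hub waste table (transcribed 2025)
newspaper,recycled,0.07,EPA GHG Emission Factors Hub waste table (transcribed 2025)
newspaper,combusted,0.11,EPA GHG Emission Factors Hub waste table (transcribed 2025)
office paper,landfilled,1.18,EPA GHG Emission Factors Hub waste table (transcribed 2025)
office paper,recycled,0.07,EPA GHG Emission Factors Hub waste table (transcribed 2025)
office paper,combusted,0.11,EPA GHG Emission Factors Hub waste table (transcribed 2025)
pet,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
pet,recycled,0.1,EPA GHG Emission Factors Hub waste table (transcribed 2025)
pet,combusted,1.24,EPA GHG Emission Factors Hub waste table (transcribed 2025)
polypropylene,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
polypropylene,recycled,0.09,EPA GHG Emission Factors Hub waste table (transcribed 2025)
polypropylene,combusted,1.34,EPA GHG Emission Factors Hub waste table (transcribed 2025)
polystyrene,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
polystyrene,combusted,1.64,EPA GHG Emission Factors Hub waste table (transcribed 2025)
pvc,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
pvc,combusted,0.69,EPA GHG Emission Factors Hub waste table (transcribed 2025)
steel cans,landfilled,0.02,EPA GHG Emission Factors Hub waste table (transcribed 2025)
steel cans,recycled,0.3,EPA GHG Emission Factors Hub waste table (transcribed 2025)
steel cans,combusted,0.01,EPA GHG Emission Factors Hub waste table (transcribed 2025)
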