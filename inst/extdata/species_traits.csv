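species,latin_name,FW_g,DW_g,area_cm2,water_loss_pct,emissivity,absorptance
avocado,Persea americana,1.359,0.533,32.404,2.499,0.960,0.949
broad bean,Vicia faba,0.446,0.052,18.846,1.151,0.993,0.875
coffee,Coffea arabica,1.606,0.523,71.727,1.159,0.973,0.948
cucumber,Cucumis sativus,2.346,0.329,110.875,NA,0.980,0.919
grapefruit,Citrus paradisi,1.455,0.500,52.914,1.019,0.948,0.952
orange,Citrus sinensis,1.294,0.555,46.005,1.602,0.947,0.952
Phalaenopsis,Phalaenopsis amabilis,6.304,0.423,48.923,0.107,0.909,0.900
pumpkin,Cucurbita maxima,3.050,NA,146.305,2.902,0.993,0.887
strawberry guava,Psidium cattleianum,0.824,0.314,21.312,0.526,0.960,0.948
sugar bean,Pisum sativum,0.203,0.030,10.447,1.161,0.985,0.910
sweet pepper,Capsicum annuum,0.921,0.122,40.019,1.309,0.997,0.928
tomato,Solanum lycopersicum,0.428,0.049,17.348,3.637,0.986,0.901
weeping fig,Ficus benjamina,0.501,0.149,24.123,0.473,0.939,0.931
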