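version,class,class_name,fun,fun_name,category,equivalent
2015,1,cultivated,food,food production,provisioning,0.85
2015,1,cultivated,raw,raw material,provisioning,0.4
2015,1,cultivated,water_sup,water supply,provisioning,0.02
2015,1,cultivated,gas,gas regulation,regulation,0.67
2015,1,cultivated,climate,climate regulation,regulation,0.36
2015,1,cultivated,purify,environment purification,regulation,0.1
2015,1,cultivated,hydro,hydrological regulation,regulation,0.27
2015,1,cultivated,soil,soil conservation,support,1.03
2015,1,cultivated,nutrient,nutrient cycle maintenance,support,0.12
2015,1,cultivated,biodiv,biodiversity protection,support,0.13
2015,1,cultivated,aesthetic,aesthetic landscape,culture,0.06
2015,2,forest,food,food production,provisioning,0.31
2015,2,forest,raw,raw material,provisioning,0.71
2015,2,forest,water_sup,water supply,provisioning,0.37
2015,2,forest,gas,gas regulation,regulation,2.35
2015,2,forest,climate,climate regulation,regulation,7.03
2015,2,forest,purify,environment purification,regulation,1.99
2015,2,forest,hydro,hydrological regulation,regulation,3.51
2015,2,forest,soil,soil conservation,support,2.86
2015,2,forest,nutrient,nutrient cycle maintenance,support,0.22
2015,2,forest,biodiv,biodiversity protection,support,2.6
2015,2,forest,aesthetic,aesthetic landscape,culture,1.14
2015,3,grassland,food,food production,provisioning,0.38
2015,3,grassland,raw,raw material,provisioning,0.56
2015,3,grassland,water_sup,water supply,provisioning,0.31
2015,3,grassland,gas,gas regulation,regulation,1.97
2015,3,grassland,climate,climate regulation,regulation,5.21
2015,3,grassland,purify,environment purification,regulation,1.72
2015,3,grassland,hydro,hydrological regulation,regulation,3.82
2015,3,grassland,soil,soil conservation,support,2.4
2015,3,grassland,nutrient,nutrient cycle maintenance,support,0.18
2015,3,grassland,biodiv,biodiversity protection,support,2.18
2015,3,grassland,aesthetic,aesthetic landscape,culture,0.96
2015,4,water,food,food production,provisioning,0.8
2015,4,water,raw,raw material,provisioning,0.23
2015,4,water,water_sup,water supply,provisioning,8.29
2015,4,water,gas,gas regulation,regulation,0.77
2015,4,water,climate,climate regulation,regulation,2.29
2015,4,water,purify,environment purification,regulation,5.55
2015,4,water,hydro,hydrological regulation,regulation,102.24
2015,4,water,soil,soil conservation,support,0.93
2015,4,water,nutrient,nutrient cycle maintenance,support,0.07
2015,4,water,biodiv,biodiversity protection,support,2.55
2015,4,water,aesthetic,aesthetic landscape,culture,1.89
2015,5,construction,food,food production,provisioning,0
2015,5,construction,raw,raw material,provisioning,0
2015,5,construction,water_sup,water supply,provisioning,0
2015,5,construction,gas,gas regulation,regulation,0
2015,5,construction,climate,climate regulation,regulation,0
2015,5,construction,purify,environment purification,regulation,0
2015,5,construction,hydro,hydrological regulation,regulation,0
2015,5,construction,soil,soil conservation,support,0
2015,5,construction,nutrient,nutrient cycle maintenance,support,0
2015,5,construction,biodiv,biodiversity protection,support,0
2015,5,construction,aesthetic,aesthetic landscape,culture,0
2015,6,unused,food,food production,provisioning,0
2015,6,unused,raw,raw material,provisioning,0
2015,6,unused,water_sup,water supply,provisioning,0
2015,6,unused,gas,gas regulation,regulation,0.02
2015,6,unused,climate,climate regulation,regulation,0
2015,6,unused,purify,environment purification,regulation,0.1
2015,6,unused,hydro,hydrological regulation,regulation,0.03
2015,6,unused,soil,soil conservation,support,0.02
2015,6,unused,nutrient,nutrient cycle maintenance,support,0
2015,6,unused,biodiv,biodiversity protection,support,0.02
2015,6,unused,aesthetic,aesthetic landscape,culture,0.01
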