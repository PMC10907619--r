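version,class,class_name,fun,fun_name,category,equivalent
2003,1,cultivated,food,food production,provisioning,1
2003,1,cultivated,raw,raw material,provisioning,0.1
2003,1,cultivated,gas,gas regulation,regulation,0.5
2003,1,cultivated,climate,climate regulation,regulation,0.89
2003,1,cultivated,water_cons,water conservation,regulation,0.6
2003,1,cultivated,waste,waste treatment,regulation,1.64
2003,1,cultivated,soil,soil formation and protection,support,1.46
2003,1,cultivated,biodiv,biodiversity protection,support,0.71
2003,1,cultivated,culture,recreation and culture,culture,0.01
2003,2,forest,food,food production,provisioning,0.1
2003,2,forest,raw,raw material,provisioning,2.6
2003,2,forest,gas,gas regulation,regulation,3.5
2003,2,forest,climate,climate regulation,regulation,2.7
2003,2,forest,water_cons,water conservation,regulation,3.2
2003,2,forest,waste,waste treatment,regulation,1.31
2003,2,forest,soil,soil formation and protection,support,3.9
2003,2,forest,biodiv,biodiversity protection,support,3.26
2003,2,forest,culture,recreation and culture,culture,1.28
2003,3,grassland,food,food production,provisioning,0.3
2003,3,grassland,raw,raw material,provisioning,0.05
2003,3,grassland,gas,gas regulation,regulation,0.8
2003,3,grassland,climate,climate regulation,regulation,0.9
2003,3,grassland,water_cons,water conservation,regulation,0.8
2003,3,grassland,waste,waste treatment,regulation,1.31
2003,3,grassland,soil,soil formation and protection,support,1.95
2003,3,grassland,biodiv,biodiversity protection,support,1.09
2003,3,grassland,culture,recreation and culture,culture,0.04
2003,4,water,food,food production,provisioning,0.1
2003,4,water,raw,raw material,provisioning,0.01
2003,4,water,gas,gas regulation,regulation,0
2003,4,water,climate,climate regulation,regulation,0.46
2003,4,water,water_cons,water conservation,regulation,20.38
2003,4,water,waste,waste treatment,regulation,18.18
2003,4,water,soil,soil formation and protection,support,0.01
2003,4,water,biodiv,biodiversity protection,support,2.49
2003,4,water,culture,recreation and culture,culture,4.34
2003,5,construction,food,food production,provisioning,0
2003,5,construction,raw,raw material,provisioning,0
2003,5,construction,gas,gas regulation,regulation,0
2003,5,construction,climate,climate regulation,regulation,0
2003,5,construction,water_cons,water conservation,regulation,0
2003,5,construction,waste,waste treatment,regulation,0
2003,5,construction,soil,soil formation and protection,support,0
2003,5,construction,biodiv,biodiversity protection,support,0
2003,5,construction,culture,recreation and culture,culture,0
2003,6,unused,food,food production,provisioning,0.01
2003,6,unused,raw,raw material,provisioning,0
2003,6,unused,gas,gas regulation,regulation,0
2003,6,unused,climate,climate regulation,regulation,0
2003,6,unused,water_cons,water conservation,regulation,0.03
2003,6,unused,waste,waste treatment,regulation,0.01
2003,6,unused,soil,soil formation and protection,support,0.02
2003,6,unused,biodiv,biodiversity protection,support,0.34
2003,6,unused,culture,recreation and culture,culture,0.01
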