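class,habitat,arable_land,construction_land,way,rural_settlement,urban_settlement
arable,0.5,0.2,0.6,0.5,0.35,0.5
woodland,1,0.3,0.8,0.7,0.7,0.6
grassland,0.9,0.5,0.4,0.5,0.55,0.3
waters,1,0.1,1,0.7,0.65,0.8
construction,0,0,0,0,0,0
unused,0.7,0.1,0.1,0.2,0.2,0.1
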