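name,max_dist_km,weight,decay,source
arable_land,0.5,0.7,linear,codes:11|12
construction_land,1,0.5,exponential,codes:53
way,2,0.6,linear,raster:road
rural_settlement,2,0.7,exponential,codes:52
urban_settlement,10,1,exponential,codes:51
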