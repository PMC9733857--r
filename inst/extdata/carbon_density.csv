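class,c_above,c_below,c_soil,c_dead
paddy_field,5.42,1.96,33.46,0
dry_land,4.7,0,33.46,0
woodland,31.92,3.38,146.82,2.96
shrubland,7.14,3.09,64.29,2
sparse_woodland,1.31,2.42,29.9,0.35
other_woodland,35.03,7.01,142.58,3.75
high_coverage_grassland,2.33,7.3,43.72,3.08
medium_coverage_grassland,3.37,7.48,44.36,4.47
low_coverage_grassland,1.66,3.41,10.93,2
lake,2.75,0,144.13,0
beach,2.3,0,146.26,0
town,0,0,0,0
rural_settlement,0,0,0,0
construction_land,0,0,0,0
bare_land,0,0,0,0
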