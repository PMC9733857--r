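code,name,primary
11,paddy_field,arable
12,dry_land,arable
21,woodland,woodland
22,shrubland,woodland
23,sparse_woodland,woodland
24,other_woodland,woodland
31,high_coverage_grassland,grassland
32,medium_coverage_grassland,grassland
33,low_coverage_grassland,grassland
42,lake,waters
46,beach,waters
51,town,construction
52,rural_settlement,construction
53,construction_land,construction
66,bare_land,unused
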