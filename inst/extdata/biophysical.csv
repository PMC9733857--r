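class,kc,root_depth_mm,vegetated
arable,1,3000,1
woodland,0.85,6000,1
grassland,0.65,1700,1
waters,1,1000,0
construction,0.3,450,0
unused,0.2,9,0
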