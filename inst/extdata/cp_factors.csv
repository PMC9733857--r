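class,c_factor,p_factor
arable,0.23,1
woodland,0.05,1
grassland,0.3,1
waters,0,0
construction,0,0
unused,1,1
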