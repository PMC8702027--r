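parent,scenario,sl_nc,sl_ca
naphthalene,recreational_sediment,20000,1e+09
acenaphthylene,recreational_sediment,30000,1e+09
acenaphthene,recreational_sediment,30000,1e+09
fluorene,recreational_sediment,30000,1e+09
phenanthrene,recreational_sediment,30000,1e+09
anthracene,recreational_sediment,30000,1e+09
fluoranthene,recreational_sediment,20000,1e+09
pyrene,recreational_sediment,30000,1e+09
benz_a_anthracene,recreational_sediment,1e+05,6000
chrysene,recreational_sediment,1e+05,6e+05
benzo_b_fluoranthene,recreational_sediment,1e+05,6000
benzo_k_fluoranthene,recreational_sediment,1e+05,60000
benzo_a_pyrene,recreational_sediment,10000,600
indeno_123cd_pyrene,recreational_sediment,1e+05,6000
dibenz_ah_anthracene,recreational_sediment,1e+05,600
benzo_ghi_perylene,recreational_sediment,1e+05,1e+09
naphthalene,residential_soil,71.4286,3571430
acenaphthylene,residential_soil,107.143,3571430
acenaphthene,residential_soil,107.143,3571430
fluorene,residential_soil,107.143,3571430
phenanthrene,residential_soil,107.143,3571430
anthracene,residential_soil,107.143,3571430
fluoranthene,residential_soil,71.4286,3571430
pyrene,residential_soil,107.143,3571430
benz_a_anthracene,residential_soil,357.143,21.4286
chrysene,residential_soil,357.143,2142.86
benzo_b_fluoranthene,residential_soil,357.143,21.4286
benzo_k_fluoranthene,residential_soil,357.143,214.286
benzo_a_pyrene,residential_soil,35.7143,2.14286
indeno_123cd_pyrene,residential_soil,357.143,21.4286
dibenz_ah_anthracene,residential_soil,357.143,2.14286
benzo_ghi_perylene,residential_soil,357.143,3571430
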