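vesicle_id,trial_id,gra_mole_percent,radius_um,sigma_mn_per_m,rupture_time_s,censored
g0.05_s8_t1_v1,trial1,0.05,15.1716006100178,8,,true
g0.05_s8_t1_v2,trial1,0.05,14.5874792239629,8,27,false
g0.05_s8_t1_v3,trial1,0.05,15.6271484298632,8,25,false
g0.05_s8_t1_v4,trial1,0.05,15.448811785318,8,2,false
g0.05_s8_t1_v5,trial1,0.05,15.509350053966,8,28,false
g0.05_s8_t1_v6,trial1,0.05,14.2001070431434,8,10,false
g0.05_s8_t2_v1,trial2,0.05,15.9421113119461,8,6,false
g0.05_s8_t2_v2,trial2,0.05,15.9244092488661,8,18,false
g0.05_s8_t2_v3,trial2,0.05,15.4290170706809,8,12,false
g0.05_s8_t2_v4,trial2,0.05,14.9639980047941,8,23,false
g0.05_s8_t2_v5,trial2,0.05,15.0274034701288,8,2,false
g0.05_s8_t2_v6,trial2,0.05,15.13422442507,8,,true
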