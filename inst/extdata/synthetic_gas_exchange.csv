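sample_id,VpdL,Tleaf,PARi,CO2S,Photo,Cond,Ci,PhiPS2
HVPD_CV1_v0.5_r1,0.5,28,1100,400,22.0606,0.77161,354.26,0.28424
HVPD_CV1_v0.5_r2,0.5,28,1100,400,22.1774,0.83843,357.68,0.28424
HVPD_CV1_v1.5_r1,1.5,28,1100,400,21.4675,0.63755,346.12,0.28424
HVPD_CV1_v1.5_r2,1.5,28,1100,400,21.6201,0.53742,335.63,0.28424
HVPD_CV1_v2.5_r1,2.5,28,1100,400,20.2525,0.3625,310.61,0.28424
HVPD_CV1_v2.5_r2,2.5,28,1100,400,20.4506,0.42751,323.46,0.28424
HVPD_CV1_v3.5_r1,3.5,28,1100,400,17.4885,0.23576,281.31,0.28424
HVPD_CV1_v3.5_r2,3.5,28,1100,400,17.9702,0.21952,269.02,0.28424
HVPD_CV1_v4.5_r1,4.5,28,1100,400,7.3058,0.05483,186.82,0.21333
HVPD_CV1_v4.5_r2,4.5,28,1100,400,7.1689,0.05422,188.47,0.21333
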