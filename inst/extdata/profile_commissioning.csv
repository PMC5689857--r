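# Lateral beam profile commissioning comparison: two configurations per
# group, each scanned at a shallow and a deep depth. Penumbra and FWHM
# differences are absolute (cm); flatness and symmetry (%) are reported
# per curve.
config,group,depth,penumbra_diff,flatness_sim,flatness_meas,symmetry_sim,symmetry_meas,fwhm_diff
1,large,10,0.03,2.9,2.0,0.6,1.9,0.12
1,large,20,0.06,2.6,2.2,0.3,0.9,0.02
5,large,5,0.06,2.7,1.9,0.1,0.9,0.01
5,large,10,0.04,2.3,1.5,0.6,0.5,0.00
13,deep,10,0.01,1.9,1.0,0.1,0.1,0.11
13,deep,20,0.01,1.2,0.6,0.3,0.2,0.13
17,deep,10,0.01,1.0,2.2,0.5,1.1,0.16
17,deep,15,0.02,1.8,1.4,0.3,1.5,0.18
18,small,10,0.02,1.1,1.5,0.1,1.2,0.02
18,small,15,0.02,1.3,1.4,0.2,0.5,0.01
20,small,5,0.03,1.2,1.6,0.6,0.4,0.15
20,small,10,0.03,1.5,0.8,0.1,0.1,0.17
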