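area,n_animals,n_cells,prop_basal,prop_oblique,prop_tuft,charge_basal_pc,charge_oblique_pc,charge_tuft_pc,total_pc,total_sem_pc,soma_depth_um,soma_depth_sem_um
VISp,6,9,0.26,0.33,0.42,0.24,0.30,0.39,0.93,0.11,507,22
V2M,4,13,0.24,0.62,0.14,2.68,6.96,1.60,11.24,1.56,498,15
RSPg,9,20,0.30,0.40,0.30,1.03,1.36,1.01,3.40,0.51,503,15
ACA,5,23,0.30,0.45,0.25,2.83,4.22,2.41,9.46,1.32,464,9
ORB,3,11,0.35,0.57,0.09,2.47,4.05,0.64,7.16,1.43,521,19
ATN,3,8,0.08,0.17,0.75,0.20,0.42,1.86,2.48,0.54,435,15
LP,4,10,0.10,0.15,0.75,0.10,0.14,0.73,0.97,0.16,500,23
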