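name	block
ipae_top_quarter	confidence
tpae_top_quarter	confidence
mean_interchain_pae	confidence
mean_iface_plddt	confidence
min_entity_mean_plddt	confidence
ptm	confidence
iptm	confidence
n_iface_total	counting
n_iface_e1	counting
n_iface_e2	counting
n_charged_interface	counting
n_charged_pos_interface	counting
n_charged_neg_interface	counting
n_polar_interface	counting
n_hydrophobic_interface	counting
n_aromatic_interface	counting
n_gly_interface	counting
n_pro_interface	counting
prop_charged_iface	counting
prop_polar_iface	counting
prop_hydrophobic_iface	counting
prop_aromatic_iface	counting
n_contact_pairs	counting
mean_pairs_per_iface_residue	counting
cp_charged_charged	counting
cp_charged_polar	counting
cp_charged_hydrophobic	counting
cp_polar_polar	counting
cp_polar_hydrophobic	counting
cp_hydrophobic_hydrophobic	counting
cp_aromatic_aromatic	counting
cp_saltbridge	counting
prop_iface_helix_e1	counting
prop_iface_beta_e1	counting
prop_iface_coil_e1	counting
prop_iface_helix_e2	counting
prop_iface_beta_e2	counting
prop_iface_coil_e2	counting
prop_iface_beta	counting
prop_iface_helix	counting
total_lj_atr	energy
avg_lj_atr	energy
total_lj_rep	energy
avg_lj_rep	energy
total_solv	energy
avg_solv	energy
total_elec	energy
avg_elec	energy
total_hbond	energy
avg_hbond	energy
total_weighted	energy
avg_weighted	energy
atr_per_contact_pair	energy
rep_per_contact_pair	energy
solv_per_contact_pair	energy
elec_per_contact_pair	energy
hbond_per_contact_pair	energy
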