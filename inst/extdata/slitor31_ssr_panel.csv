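molecule,prediction,active
2-methoxy-4-propylphenol,binder,1
predicted_binder_01,binder,0
predicted_binder_02,binder,0
predicted_binder_03,binder,0
predicted_binder_04,binder,0
predicted_binder_05,binder,0
predicted_binder_06,binder,0
predicted_binder_07,binder,0
predicted_binder_08,binder,0
predicted_binder_09,binder,0
predicted_binder_10,binder,0
predicted_binder_11,binder,0
predicted_binder_12,binder,0
predicted_binder_13,binder,0
predicted_binder_14,binder,0
predicted_binder_15,binder,0
predicted_binder_16,binder,0
suspected_decoy_01,suspected_decoy,0
suspected_decoy_02,suspected_decoy,0
suspected_decoy_03,suspected_decoy,0
potential_nonbinder_01,potential_nonbinder,0
potential_nonbinder_02,potential_nonbinder,0
potential_nonbinder_03,potential_nonbinder,0
potential_nonbinder_04,potential_nonbinder,0
potential_nonbinder_05,potential_nonbinder,0
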