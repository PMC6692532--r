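source	true_value	observed_value
entity_detection_error	633074	582428
entity_absent_in_text	633074	615650
failure_to_detect_entity	633074	609413
gene_normalization_error	42607	50336
disease_normalization_error	71704	92481
drug_normalization_error	11033	14563
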