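# B0-direction reversal composite: conjugate RF, flip the z gradient axis.
# Channel ordering is site-specific; edit channel_permutation to match the
# coil plug mapping of your systems (identity shipped).
gradient_transform 1 0 0 0 1 0 0 0 -1
rf_conjugate 1
b0_flip 1
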