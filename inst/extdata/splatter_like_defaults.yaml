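# splatter-like defaults for the count simulator
#
# These mirror the published defaults of the Splatter gamma-Poisson
# simulator and are a convention, not values fitted to any dataset; every
# field can be overridden through simulation_params().
n_genes: 2000
n_cells: 500
n_groups: 5
outlier_prob: 0.05
mean_shape: 0.6
mean_rate: 0.3
outlier_fac_loc: 4.0
outlier_fac_scale: 0.5
lib_loc: 11.0
lib_scale: 0.2
de_prob: 0.1
de_fac_loc: 0.1
de_fac_scale: 0.4
de_down_prob: 0.5
dropout_enabled: false
dropout_mid: 0.0
dropout_shape: -1.0
dispersion: 0.0
seed: 1
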