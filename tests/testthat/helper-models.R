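# Canonical single-neuron models used across tests: the packaged
# bias-driven set (dataset 1) and spike-driven set (dataset 2).
d1_params <- function() lif_table1()[["1"]]
d2_params <- function() lif_table1()[["2"]]

default_cfg <- function(...) mapping_config(...)

# A compartment with hand-set fixed-point fields, for contract tests of
# the step arithmetic that need exact control over each word (synthetic,
# not produced by the parameter mapping).
synthetic_comp <- function(delta_v = 164, delta_u = 2048, theta_eff = 270016,
                           bias_eff = 0, params = d1_params(),
                           cfg = default_cfg()) {
  structure(list(delta_v = delta_v, delta_v_stored = delta_v %% 4096,
                 delta_u = delta_u, delta_u_stored = delta_u %% 4096,
                 theta_mant = theta_eff / 64, theta_eff = theta_eff,
                 bias_mant = bias_eff, bias_exp = 0L, bias_eff = bias_eff,
                 bias_target = bias_eff, params = params, cfg = cfg),
            class = "loihi_compartment")
}
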