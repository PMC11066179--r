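# Named model presets: the published parameter columns of the optimized
# and original F-MF, D-MF and grid models, plus the SSSF baseline.
# `reported` carries the published 20-run summary metrics for reference
# (fields/neuron, energy, median/min/max positional error in meters).
#
# The `assumed` section holds constants that the source tables do not
# print (they were supplementary material): they are this package's own
# documented defaults, exposed so reproduction caveats are explicit.

assumed:
  tau_s: 0.1
  dt_s: 0.01
  i_pos: 1.0
  speed_mps: 10.0
  theta_field: 0.2
  lateral:            # default lateral-weight constants for "+" variants
    sssf: {w_exc: 0.2, w_inh: 0.05}
    fmf:  {w_exc: 0.2, w_inh: 0.05}
    dmf:  {w_exc: 0.2, w_inh: 0.05}
  background:
    i_bck: 0.1

presets:
  F-Opt-1:
    family: FMF
    params: {n_al_0: 50, n_al_1: 48, n_al_2: 50, p_att: 0.95, n_neurons: 50}
    reported: {n_f: 140.6, c_eng: 140.8, e_pos_median: 0.000,
               e_pos_min: 0.000, e_pos_max: 0.003}
  F-Opt-2:
    family: FMF
    params: {n_al_0: 50, n_al_1: 22, n_al_2: 40, p_att: 0.40, n_neurons: 50}
    reported: {n_f: 44.8, c_eng: 60.0, e_pos_median: 0.000,
               e_pos_min: 0.000, e_pos_max: 0.004}
  F-Opt-3:
    family: FMF
    params: {n_al_0: 11, n_al_1: 10, n_al_2: 9, p_att: 0.40, n_neurons: 50}
    reported: {n_f: 12.0, c_eng: 59.6, e_pos_median: 0.150,
               e_pos_min: 0.133, e_pos_max: 0.279}
  F-Org-1:
    family: FMF
    params: {n_al_0: 5, n_al_1: 2, n_al_2: 1, p_att: 0.30, n_neurons: 4000}
    reported: {n_f: 2.4, c_eng: 3460.6, e_pos_median: 0.098,
               e_pos_min: 0.085, e_pos_max: 0.110}
  F-Org-2:
    family: FMF
    params: {n_al_0: 5, n_al_1: 2, n_al_2: 1, p_att: 0.30, n_neurons: 50}
    reported: {n_f: 2.4, c_eng: 43.8, e_pos_median: 1.148,
               e_pos_min: 1.056, e_pos_max: 1.293}
  D-Opt-1:
    family: DMF
    params: {shape: 15.92, scale: 0.02, sum_fs: 36, n_neurons: 50,
             th_fsr: 0.9}
    reported: {n_f: 114, c_eng: 89.5, e_pos_median: 0.300,
               e_pos_min: 0.009, e_pos_max: 1.580}
  D-Org-1:
    family: DMF
    params: {shape: 3.16, scale: 1.80, sum_fs: 30, n_neurons: 50,
             th_fsr: 0.9}
    reported: {n_f: 7.13, c_eng: 74.2, e_pos_median: 1.265,
               e_pos_min: 0.866, e_pos_max: 3.141}
  G-Opt-1:
    family: GRID
    params: {n_modules: 3, n_per_module: 9, scale_factor: 1.6,
             min_scale: 0.5}
    reported: {n_f: 29.852, c_eng: 30.75, e_pos_median: 0.0,
               e_pos_min: 0.0, e_pos_max: 0.0}
  G-Opt-2:
    family: GRID
    params: {n_modules: 9, n_per_module: 19, scale_factor: 3.0,
             min_scale: 0.5}
    reported: {n_f: 3.509, c_eng: 64.57, e_pos_median: 0.0,
               e_pos_min: 0.0, e_pos_max: 0.0}
  G-Opt-3:
    family: GRID
    params: {n_modules: 9, n_per_module: 7, scale_factor: 3.0,
             min_scale: 0.5}
    reported: {n_f: 9.524, c_eng: 64.64, e_pos_median: 0.0,
               e_pos_min: 0.0, e_pos_max: 0.0}
  G-Opt-4:
    family: GRID
    params: {n_modules: 3, n_per_module: 19, scale_factor: 1.2,
             min_scale: 0.5}
    reported: {n_f: 17.737, c_eng: 30.76, e_pos_median: 0.0,
               e_pos_min: 0.0, e_pos_max: 0.0}
  G-Opt-5:
    family: GRID
    params: {n_modules: 3, n_per_module: 19, scale_factor: 1.8,
             min_scale: 0.5}
    reported: {n_f: 13.07, c_eng: 30.73, e_pos_median: 0.0,
               e_pos_min: 0.0, e_pos_max: 0.0}
  S-Std-1:
    family: SSSF
    params: {n_neurons: 50}
    reported: {}
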