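# Shared fixtures: the default mouse parameterisation and target curve.
mouse <- kinetic_params()
study_target <- make_target_series()

# Final Abeta level under doses applied to one or more parameters,
# all starting at `t_start` (months).
a27_at <- function(params, doses, t_start = 1, base = mouse) {
  ivs <- Map(function(p, d) intervention(p, d, t_start), params, doses)
  traj <- run_intervention(base, ivs, eval_times = 27)
  traj$A[nrow(traj)]
}
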