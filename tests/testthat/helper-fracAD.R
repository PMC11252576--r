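# shared helpers for the suite

ad_rhs_fn <- function(params = ad_parameters()) {
  function(t, y) ad_rhs(y, params)
}

endpoint <- function(traj) traj$states[nrow(traj$states), ]

max_rel_dev <- function(x, ref) max(abs(x - ref) / pmax(abs(ref), 1))
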