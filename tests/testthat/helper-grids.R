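# dense sampling grids used by the oracle-style tests; fine spacing over the
# absorption phase, coarser over the tail
dense_grid <- function(t_max = 96, dt_early = 0.05, dt_late = 0.5,
                       t_switch = 12) {
  sort(unique(c(seq(dt_early, t_switch, by = dt_early),
                seq(t_switch + dt_late, t_max, by = dt_late))))
}

# random positive parameter sets for property-style loops
random_pk_params <- function(n, seed) {
  set.seed(seed)
  purrr::map(seq_len(n), function(i) {
    ka <- stats::runif(1, 0.1, 5)
    pk_params(
      ka = ka,
      kd = stats::runif(1, 0.05, 2),
      v = stats::runif(1, 5, 200),
      dose = stats::runif(1, 10, 1000),
      f = stats::runif(1, 0.2, 1),
      kgut = ka * stats::runif(1, 1, 4)
    )
  })
}
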