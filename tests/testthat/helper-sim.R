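# small, fast simulator configs shared across tests

quiet_cfg <- function(n = 100, seed = 1, ...) {
  args <- utils::modifyList(
    list(n_proteins = n, noise_cv = 0, batch_sigma = 0,
         missing_rate_mcar = 0, missing_intensity_alpha = 0,
         absent_fraction = 0, include_spike = FALSE, seed = seed),
    list(...))
  do.call(sim_config, args)
}

noisy_cfg <- function(n = 200, seed = 1, ...) {
  sim_config(n_proteins = n, seed = seed, ...)
}

# brute-force Fisher enumeration over all tables with the observed margins
fisher_brute <- function(tab, side) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x)
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1), numeric(1))
  p_obs <- pr[xs == a]
  switch(side,
         over = sum(pr[xs >= a]),
         under = sum(pr[xs <= a]),
         two_sided = min(1, sum(pr[pr <= p_obs * (1 + 1e-7)])))
}
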