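# compact fixtures built in code

small_sim <- function(seed = 1, n = 30, ...) {
  simulation_config(n_patients = n, n_proteins = 20, n_clones = 45,
                    n_signature_proteins = 3, rng_seed = seed, ...)
}

# plain exponential survival fixture
exp_surv <- function(n, seed, rate = 0.1, cens_rate = 0.05) {
  withr::with_seed(seed, {
    t_ev <- rexp(n, rate)
    t_c <- rexp(n, cens_rate)
    surv_data(pmin(t_ev, t_c), as.integer(t_ev <= t_c))
  })
}

# spot table for one sample and a vector of replicate triplets
triplet_spots <- function(triplets, bg = 0) {
  do.call(rbind, lapply(seq_along(triplets), function(i) {
    data.table::data.table(sample_id = "S1",
                           analyte_id = sprintf("A%02d", i),
                           replicate = 1:3,
                           fg = triplets[[i]] + bg, bg = bg, flag = "ok")
  }))
}
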