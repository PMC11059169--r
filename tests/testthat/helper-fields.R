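# Shared fixtures: random small states and an independent numerical
# functional-derivative oracle for the molecular field.

random_q <- function(n, seed, amp = 0.5) {
  set.seed(seed)
  qtensor_field(matrix(runif(n * n, -amp, amp), n, n),
                matrix(runif(n * n, -amp, amp), n, n))
}

random_state <- function(n, seed) {
  list(Qn = random_q(n, seed), Qm = random_q(n, seed + 1000))
}

# Central-difference derivative of the discrete free energy with respect to
# each independent Q component; the molecular field must equal -dF/dQ_c / 2
# (each off/on-diagonal component enters the tensor contraction twice).
numerical_molecular_field <- function(Qn, Qm, params, which = "n",
                                      interior = NULL, h = 1e-6) {
  Q <- if (which == "n") Qn else Qm
  num <- list(xx = matrix(0, nrow(Q$xx), ncol(Q$xx)),
              xy = matrix(0, nrow(Q$xx), ncol(Q$xx)))
  for (comp in c("xx", "xy")) {
    for (k in seq_along(Q$xx)) {
      for (sgn in c(1, -1)) {
        Qp <- Q
        Qp[[comp]][k] <- Qp[[comp]][k] + sgn * h
        args <- if (which == "n") list(Qp, Qm) else list(Qn, Qp)
        e <- total_free_energy(args[[1]], args[[2]], params, interior)
        num[[comp]][k] <- num[[comp]][k] + sgn * e / (2 * h)
      }
    }
  }
  qtensor_field(-num$xx / 2, -num$xy / 2)
}

# Memoised scaled-down MDCK run shared by the acceptance checks.
acceptance_cache <- new.env(parent = emptyenv())

scaled_mdck_run <- function() {
  if (is.null(acceptance_cache$summary)) {
    cfg <- run_config(grid = 128, steps = 39900, frame_every = 300,
                      seed = 11, store_flow = FALSE)
    traj <- simulate_monolayer(cfg)
    acceptance_cache$summary <- summarize_run(traj, measure = 50)
  }
  acceptance_cache$summary
}
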