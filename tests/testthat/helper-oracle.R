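# Independent reference integrator for the contagion model, written directly
# from the model definition in plain R: explicit Euler, division when A
# crosses theta (linear interpolation within the step), neighbour counts
# updated after the step in which a cell divides. Used to cross-check the
# compiled integrator.
r_simulate_arm <- function(n, r, mu, rho, delta, theta, dt, t_max,
                           open_end = FALSE) {
  A <- rep(0, n)
  m <- rep(2L, n)
  if (open_end) m[n] <- 1L
  I <- mu * delta * m
  m[1L] <- m[1L] - 1L  # the seed divides at t = 0
  div <- rep(NA_real_, n)
  divided <- rep(FALSE, n)
  for (s in seq_len(ceiling(t_max / dt))) {
    t <- (s - 1) * dt
    A_old <- A
    upd <- !divided
    A[upd] <- A[upd] + dt * (r / (1 + I[upd]) - A[upd] / rho)
    I[upd] <- I[upd] + dt * (mu * m[upd] - I[upd] / delta)
    crossed <- which(upd & A >= theta)
    for (i in crossed) {
      frac <- if (A[i] > A_old[i]) (theta - A_old[i]) / (A[i] - A_old[i]) else 1
      div[i] <- t + dt * frac
      divided[i] <- TRUE
    }
    for (i in crossed) {
      if (i > 1L) m[i - 1L] <- m[i - 1L] - 1L
      if (i < n) m[i + 1L] <- m[i + 1L] - 1L
    }
    if (all(divided)) break
  }
  div
}

# A small valid observation table: two nota, two rows each.
make_toy_dataset <- function(seed = 42L, n_nota = 2L, n_rows = 2L,
                             n_sops = 5L) {
  withr::with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(n_nota), function(nt) {
      do.call(rbind, lapply(seq_len(n_rows), function(rw) {
        pos <- round(cumsum(runif(n_sops, 20, 40)), 3)
        tibble::tibble(notum_id = paste0("n", nt),
                       row_id = paste0("R", rw),
                       side = sample(c("left", "right", "unspecified"), 1),
                       position_um = pos,
                       division_time_min = round(runif(n_sops, 0, 120), 3),
                       genotype = "toy")
      }))
    }))
    notum_dataset(recs)
  })
}

# Exact linear wave: time = s_min_per_um * |metric rank|.
make_linear_series <- function(s_min_per_um, n_ant = 4L, n_post = 6L,
                               spacing_um = 30) {
  rank <- c(-rev(seq_len(n_ant)), 0L, seq_len(n_post))
  new_rank_series(rank, s_min_per_um * abs(rank) * spacing_um,
                  spacing_um = spacing_um)
}
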