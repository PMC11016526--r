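# Independent microsimulation oracle: propagates n individual patients
# through the same per-age transition matrices and tabulates the empirical
# state distribution per cycle. Written against the matrix interface only;
# it shares no code with the cohort-trace propagation it checks.
microsim_trace <- function(p, strategy, cfg, n = 200000, seed = 1) {
  states <- c("RA", "MI", "CAr", "Rv", "D")
  end_age <- if (cfg$over_84_rule == "truncate") min(cfg$max_age, 85L)
             else cfg$max_age
  n_cyc <- end_age - cfg$start_age
  occ <- matrix(0, n_cyc + 1L, 5L, dimnames = list(NULL, states))
  cur <- rep.int(1L, n)
  occ[1L, ] <- tabulate(cur, 5L) / n
  set.seed(seed)
  for (t in seq_len(n_cyc)) {
    M <- transition_matrix(p, strategy, cfg$start_age + t - 1L, cfg)
    cum <- t(apply(M, 1L, cumsum))
    u <- runif(n)
    nxt <- integer(n)
    for (s in 1:5) {
      idx <- which(cur == s)
      if (length(idx))
        nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    cur <- nxt
    occ[t + 1L, ] <- tabulate(cur, 5L) / n
  }
  occ
}

# parameter table with every standard error removed (degenerate PSA)
zero_se_parameters <- function(p = acs_parameters()) {
  q <- as.data.frame(p)
  q$se <- ifelse(is.na(q$se), NA, 0)
  as_acs_parameters(q)
}

expect_row_stochastic <- function(M, tol = 1e-10) {
  expect_true(all(M >= 0))
  expect_true(all(abs(rowSums(M) - 1) < tol))
}
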