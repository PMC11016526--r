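# Synthetic parameter-table generator: random but structurally valid inputs,
# so every pipeline stage can be exercised independently of the packaged
# reference table.

# evaluate expr under a temporary RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random, structurally valid parameter table
#'
#' Draws a complete parameter set with the statistical structure the model
#' assumes: every from-state row feasible in every age band, event-to-death
#' probabilities non-decreasing in age, positive costs, utilities strictly
#' inside (0, 1), hazard ratios in (0.3, 1.5), and standard errors small
#' enough that beta/gamma/lognormal moment matching is well defined. The
#' \code{"extreme"} difficulty pushes values toward their bounds
#' (near-0/near-1 probabilities, hazard ratios near 1, steep mortality) to
#' exercise edge cases; rows remain feasible by construction.
#'
#' @param seed integer seed; the same seed always yields the identical table.
#' @param difficulty \code{"typical"} or \code{"extreme"}.
#' @return A validated \code{acs_parameters} object.
#' @examples
#' p <- random_parameters(1)
#' nrow(validate_parameters(p)) == 0
#' @export
random_parameters <- function(seed, difficulty = c("typical", "extreme")) {
  difficulty <- match.arg(difficulty)
  .with_seed(seed, .random_parameters_impl(difficulty))
}

.random_parameters_impl <- function(difficulty) {
  ext <- difficulty == "extreme"
  ru <- function(lo, hi) stats::runif(1, lo, hi)
  # standard error as a feasible fraction of the beta bound
  se_prob <- function(m, frac_hi = 0.3) {
    if (m <= 0 || m >= 1) return(0)
    stats::runif(1, 0.02, frac_hi) * sqrt(m * (1 - m))
  }

  # Resolved-ACS event row; stay probability is the residual
  if (ext) {
    tpRA_MI <- ru(1e-4, 0.09)
    tpRA_CAr <- ru(1e-5, 0.02)
    tpRA_Rv <- ru(1e-4, 0.12)
  } else {
    tpRA_MI <- ru(0.005, 0.03)
    tpRA_CAr <- ru(5e-4, 0.005)
    tpRA_Rv <- ru(0.01, 0.06)
  }
  tpRA_RA <- 1 - (tpRA_MI + tpRA_CAr + tpRA_Rv)

  # recurrent-event probabilities
  tpMI_MI <- if (ext) ru(1e-3, 0.2) else ru(0.02, 0.10)
  tpMI_Rv <- if (ext) ru(1e-3, 0.15) else ru(0.01, 0.05)
  tpRv_Rv <- if (ext) ru(1e-3, 0.3) else ru(0.05, 0.20)
  tpRv_MI <- if (ext) ru(1e-3, 0.5) else ru(0.20, 0.45)

  # age-banded death probabilities: geometric growth across the 11 bands,
  # capped so each row keeps positive residual mass in its worst band
  mort <- function(stay_other) {
    base <- if (ext) ru(5e-4, 0.03) else ru(0.003, 0.010)
    growth <- if (ext) ru(1.3, 1.75) else ru(1.2, 1.5)
    d <- base * growth^(0:10)
    cap <- 0.98 - stay_other
    if (max(d) > cap) d <- d * (cap / max(d))
    d
  }
  dMI <- mort(tpMI_MI + tpMI_Rv)
  dCAr <- mort(0)
  dRv <- mort(tpRv_Rv + tpRv_MI)

  # costs (IDR per cycle / per year)
  rcost <- function(lo, hi) ru(lo, hi)
  dmc <- if (ext) c(rcost(1e5, 8e7), rcost(1e5, 8e7), rcost(1e5, 8e7),
                    rcost(1e5, 8e7))
         else c(rcost(5e6, 4e7), rcost(5e6, 3e7), rcost(2e6, 2e7),
                rcost(1e7, 6e7))
  cHIS <- if (ext) rcost(1e5, 1e7) else rcost(2e6, 6e6)
  cNHIS <- ru(if (ext) 1e4 else 5e5, cHIS)

  # hazard ratios for the high-intensity arm
  hr1 <- function() if (ext && stats::runif(1) < 0.5) ru(0.95, 1.05)
                    else ru(0.35, 1.45)
  HRs <- c(hr1(), hr1(), hr1())

  # utilities; event states no better than the resolved state
  uRA <- if (ext) ru(0.4, 0.98) else ru(0.6, 0.9)
  uMI <- ru(if (ext) 0.02 else 0.35, uRA)
  uCAr <- ru(if (ext) 0.02 else 0.35, uRA)
  uRv <- ru(if (ext) 0.02 else 0.45, uRA)

  dr <- c(ru(0, 0.05), ru(0, 0.05))

  base <- acs_parameters()
  p <- as.data.frame(base)
  setm <- function(name, m, s = NULL) {
    i <- match(name, p$name)
    p$mean[i] <<- m
    if (!is.null(s)) p$se[i] <<- s
  }
  setm("drC", dr[1], NA); setm("drO", dr[2], NA)
  setm("tpRA_RA", tpRA_RA, se_prob(tpRA_RA))
  setm("tpRA_MI", tpRA_MI, se_prob(tpRA_MI))
  setm("tpRA_CAr", tpRA_CAr, se_prob(tpRA_CAr))
  setm("tpRA_Rv", tpRA_Rv, se_prob(tpRA_Rv))
  setm("tpMI_MI", tpMI_MI, se_prob(tpMI_MI))
  setm("tpMI_Rv", tpMI_Rv, se_prob(tpMI_Rv))
  setm("tpRv_Rv", tpRv_Rv, se_prob(tpRv_Rv))
  setm("tpRv_MI", tpRv_MI, se_prob(tpRv_MI))
  for (st in .EVENT_STATES) {
    d <- switch(st, MI = dMI, CAr = dCAr, Rv = dRv)
    syms <- .mortality_symbols(st)
    for (b in 1:11) setm(syms[b], d[b], se_prob(d[b], 0.2))
  }
  setm("dmcRA", dmc[1], dmc[1] * ru(0.01, 0.2))
  setm("dmcMI", dmc[2], dmc[2] * ru(0.01, 0.2))
  setm("dmcCAr", dmc[3], dmc[3] * ru(0.01, 0.2))
  setm("dmcRv", dmc[4], dmc[4] * ru(0.01, 0.2))
  setm("cHIS", cHIS, cHIS * ru(0.02, 0.2))
  setm("cNHIS", cNHIS, cNHIS * ru(0.02, 0.2))
  setm("HR_HIS_MI", HRs[1], HRs[1] * ru(0.05, 0.2))
  setm("HR_HIS_CAr", HRs[2], HRs[2] * ru(0.05, 0.2))
  setm("HR_HIS_Rv", HRs[3], HRs[3] * ru(0.05, 0.2))
  setm("uRA", uRA, se_prob(uRA))
  setm("uMI", uMI, se_prob(uMI))
  setm("uCAr", uCAr, se_prob(uCAr))
  setm("uRv", uRv, se_prob(uRv))
  as_acs_parameters(p)
}
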