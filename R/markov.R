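# Markov cohort engine: per-strategy, per-age-band transition matrices and
# the lifetime cohort trace.

.STRATEGIES <- c("HIS", "LMIS")

#' Model run configuration
#'
#' Collects the cohort settings and the structural conventions of the Markov
#' engine. The cohort enters the model at \code{start_age} (years) entirely
#' in the Resolved-ACS state and is followed in one-year cycles until
#' \code{max_age}. The remaining switches settle conventions that a
#' state-transition diagram and a parameter table do not pin down by
#' themselves:
#'
#' \describe{
#'   \item{residual_rule}{where the unlisted survivor mass of an event-state
#'     row goes: back to Resolved ACS (\code{"to_RA"}, default), stay in the
#'     event state (\code{"stay"}), or to Death (\code{"to_D"}, an
#'     exploratory high-mortality reading).}
#'   \item{hr_transform}{how a hazard ratio acts on an annual probability:
#'     \code{"multiplicative"} (\eqn{\min(hr \cdot p, 1)}, default) or
#'     \code{"rate_based"} (\eqn{1-(1-p)^{hr}}).}
#'   \item{hr_scope}{which transitions the high-intensity-statin hazard
#'     ratios modify: every transition into the event state
#'     (\code{"all_inbound"}, default) or only first events from Resolved
#'     ACS (\code{"from_RA_only"}).}
#'   \item{half_cycle_correction}{if \code{TRUE}, the first and last cycle
#'     accrue half weight.}
#'   \item{over_84_rule}{what to do past the last 80-84 mortality band:
#'     keep using it (\code{"hold_last_band"}, default) or truncate the
#'     horizon at age 85 (\code{"truncate"}).}
#' }
#'
#' @param start_age cohort entry age in years (at least 30).
#' @param max_age final age of the simulation; \code{max_age = start_age}
#'   gives a degenerate single-cycle run.
#' @param cycle_length cycle length in years; the model is annual, so this
#'   is fixed at 1.
#' @param residual_rule,hr_transform,hr_scope,half_cycle_correction,over_84_rule
#'   structural conventions, see Details.
#' @param discount_cost,discount_outcome optional annual discount-rate
#'   overrides; \code{NULL} (default) uses the rates in the parameter table.
#' @param wtp willingness-to-pay thresholds (IDR per QALY) used by default
#'   for acceptability curves and net-monetary-benefit summaries; defaults
#'   are the Indonesian willingness-to-pay for life-saving disease and three
#'   times GDP per capita.
#' @param cohort_size reporting scale for absolute counts (the engine tracks
#'   proportions; results are per patient unless scaled).
#' @return An object of class \code{acs_config}.
#' @export
model_config <- function(start_age = 30L,
                         max_age = 100L,
                         cycle_length = 1,
                         residual_rule = c("to_RA", "stay", "to_D"),
                         hr_transform = c("multiplicative", "rate_based"),
                         hr_scope = c("all_inbound", "from_RA_only"),
                         half_cycle_correction = FALSE,
                         over_84_rule = c("hold_last_band", "truncate"),
                         discount_cost = NULL,
                         discount_outcome = NULL,
                         wtp = c(192514839, 206319831.79),
                         cohort_size = 1000L) {
  start_age <- as.integer(start_age)
  max_age <- as.integer(max_age)
  if (is.na(start_age) || start_age < 30L)
    stop("start_age must be an integer >= 30")
  if (is.na(max_age) || max_age < start_age)
    stop("max_age must be >= start_age")
  if (!identical(as.numeric(cycle_length), 1))
    stop("cycle_length is fixed at 1 year in this model")
  stopifnot(is.logical(half_cycle_correction), length(half_cycle_correction) == 1)
  for (r in c(discount_cost, discount_outcome))
    if (!is.null(r) && (!is.finite(r) || r < 0))
      stop("discount rates must be nonnegative")
  wtp <- as.numeric(unlist(wtp))   # tolerate JSON-manifest lists
  if (length(wtp) == 0 || any(!is.finite(wtp)) || any(wtp < 0))
    stop("wtp thresholds must be nonnegative")
  structure(list(
    start_age = start_age,
    max_age = max_age,
    cycle_length = 1,
    residual_rule = match.arg(residual_rule),
    hr_transform = match.arg(hr_transform),
    hr_scope = match.arg(hr_scope),
    half_cycle_correction = isTRUE(half_cycle_correction),
    over_84_rule = match.arg(over_84_rule),
    discount_cost = discount_cost,
    discount_outcome = discount_outcome,
    wtp = as.numeric(wtp),
    cohort_size = as.integer(cohort_size)
  ), class = "acs_config")
}

#' @export
print.acs_config <- function(x, ...) {
  cat(sprintf("Model configuration: ages %d-%d, 1-year cycles\n",
              x$start_age, x$max_age))
  cat(sprintf("  residual_rule=%s, hr_transform=%s, hr_scope=%s\n",
              x$residual_rule, x$hr_transform, x$hr_scope))
  cat(sprintf("  half_cycle_correction=%s, over_84_rule=%s\n",
              x$half_cycle_correction, x$over_84_rule))
  cat("  WTP thresholds (IDR/QALY):",
      paste(format(x$wtp, big.mark = ",", scientific = FALSE),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read a run configuration from a YAML file
#'
#' Unknown keys are rejected; recognized keys are passed to
#' \code{\link{model_config}}.
#'
#' @param path YAML file.
#' @return An \code{acs_config} object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  legal <- names(formals(model_config))
  unknown <- setdiff(names(y), legal)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(model_config, y)
}

# 1-based band index for the 11 five-year mortality bands
.band_index <- function(age, over_84_rule = "hold_last_band") {
  if (any(age < 30)) stop("age below 30 is outside the model's age range")
  b <- (as.integer(age) - 30L) %/% 5L + 1L
  over <- b > 11L
  if (any(over)) {
    if (over_84_rule == "hold_last_band") b[over] <- 11L
    else stop("age beyond 84 has no mortality band under over_84_rule='truncate'")
  }
  b
}

#' Age band containing an age
#'
#' The event-to-death probabilities are tabulated in 5-year bands from
#' 30-34 to 80-84. Ages of 85 and above either reuse the last band
#' (\code{"hold_last_band"}) or are an error (\code{"truncate"}).
#'
#' @param age age in years (>= 30).
#' @param over_84_rule see \code{\link{model_config}}.
#' @return Band label such as \code{"30-34"} (vectorized).
#' @examples
#' age_band_for(30)  # "30-34"
#' age_band_for(92)  # "80-84"
#' @export
age_band_for <- function(age, over_84_rule = c("hold_last_band", "truncate")) {
  over_84_rule <- match.arg(over_84_rule)
  b <- .band_index(age, over_84_rule)
  sprintf("%d-%d", .BAND_STARTS[b], .BAND_STARTS[b] + 4L)
}

#' Apply a hazard ratio to an annual transition probability
#'
#' \code{"multiplicative"} returns \eqn{\min(hr \cdot p, 1)};
#' \code{"rate_based"} converts the probability to a rate, scales it, and
#' converts back: \eqn{1 - (1-p)^{hr}}.
#'
#' @param p annual probability in \eqn{[0, 1]} (vectorized).
#' @param hr hazard ratio (> 0).
#' @param transform transformation convention.
#' @return Transformed probability in \eqn{[0, 1]}.
#' @examples
#' apply_hazard_ratio(0.012, 0.77)                # 0.00924
#' apply_hazard_ratio(0.012, 0.77, "rate_based")  # 1 - 0.988^0.77
#' @export
apply_hazard_ratio <- function(p, hr,
                               transform = c("multiplicative", "rate_based")) {
  transform <- match.arg(transform)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]")
  if (any(!is.finite(hr)) || any(hr <= 0))
    stop("hazard ratios must be positive")
  if (transform == "multiplicative") pmin(hr * p, 1) else 1 - (1 - p)^hr
}

#' Transition matrix for one strategy at one age
#'
#' Builds the 5x5 row-stochastic matrix over (RA, MI, CAr, Rv, D) from the
#' parameter table. Under the high-intensity-statin strategy the relevant
#' hazard ratios transform the event transitions according to
#' \code{cfg$hr_scope} and \code{cfg$hr_transform}. The stay/return residual
#' of each row is recomputed after transformation; if the listed outgoing
#' mass of a row exceeds 1 it is rescaled proportionally to sum to 1 and the
#' number of rescaled rows is recorded in the \code{"rescaled"} attribute.
#'
#' @param p parameter set.
#' @param strategy \code{"HIS"} or \code{"LMIS"}.
#' @param age age in years at the start of the cycle.
#' @param cfg model configuration.
#' @return 5x5 numeric matrix with dimnames, attributes \code{strategy},
#'   \code{age} and \code{rescaled}.
#' @export
transition_matrix <- function(p, strategy = .STRATEGIES, age,
                              cfg = model_config()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cfg, "acs_config"))
  if (age < cfg$start_age) stop("age below the configured start_age")
  b <- .band_index(age, cfg$over_84_rule)
  .build_matrix(.engine_params(p), strategy, b, cfg)
}

# flatten the parameter table into plain vectors for the inner loop
.engine_params <- function(p) {
  stopifnot(inherits(p, "acs_parameters"))
  list(
    tpRA = .pmean(p, c("tpRA_MI", "tpRA_CAr", "tpRA_Rv")),
    tpMI = .pmean(p, c("tpMI_MI", "tpMI_Rv")),
    tpRv = .pmean(p, c("tpRv_Rv", "tpRv_MI")),
    mort = list(MI = .mortality_means(p, "MI"),
                CAr = .mortality_means(p, "CAr"),
                Rv = .mortality_means(p, "Rv")),
    hr = .pmean(p, c("HR_HIS_MI", "HR_HIS_CAr", "HR_HIS_Rv")),
    dmc = c(.pmean(p, c("dmcRA", "dmcMI", "dmcCAr", "dmcRv")), 0),
    drug = .pmean(p, c("cHIS", "cNHIS")),
    u = c(.pmean(p, c("uRA", "uMI", "uCAr", "uRv")), 0),
    dr = .pmean(p, c("drC", "drO"))
  )
}

# ep: .engine_params() list; b: band index
.build_matrix <- function(ep, strategy, b, cfg) {
  his <- strategy == "HIS"
  tf <- cfg$hr_transform
  hrMI <- ep$hr[1]; hrCAr <- ep$hr[2]; hrRv <- ep$hr[3]
  # hazard ratio on a transition into an event state
  h <- function(pr, hr, from_RA) {
    if (his && (cfg$hr_scope == "all_inbound" || from_RA))
      apply_hazard_ratio(pr, hr, tf)
    else pr
  }
  M <- matrix(0, 5, 5, dimnames = list(.STATES, .STATES))
  rescaled <- 0L

  # Resolved ACS: stay probability is the residual; no direct death exit
  ev <- c(h(ep$tpRA[1], hrMI, TRUE), h(ep$tpRA[2], hrCAr, TRUE),
          h(ep$tpRA[3], hrRv, TRUE))
  if (sum(ev) > 1) { ev <- ev / sum(ev); rescaled <- rescaled + 1L }
  M["RA", ] <- c(1 - sum(ev), ev[1], ev[2], ev[3], 0)

  res_target <- switch(cfg$residual_rule, to_RA = "RA", to_D = "D", stay = NA)
  fill_event_row <- function(from, listed) {
    tot <- sum(listed)
    if (tot > 1) {
      listed <- listed / tot
      rescaled <<- rescaled + 1L
      tot <- 1
    }
    M[from, names(listed)] <<- M[from, names(listed)] + listed
    resid <- 1 - tot
    tgt <- if (is.na(res_target)) from else res_target
    M[from, tgt] <<- M[from, tgt] + resid
  }
  fill_event_row("MI", c(MI = h(ep$tpMI[1], hrMI, FALSE),
                         Rv = h(ep$tpMI[2], hrRv, FALSE),
                         D = ep$mort$MI[b]))
  fill_event_row("CAr", c(D = ep$mort$CAr[b]))
  fill_event_row("Rv", c(Rv = h(ep$tpRv[1], hrRv, FALSE),
                         MI = h(ep$tpRv[2], hrMI, FALSE),
                         D = ep$mort$Rv[b]))
  M["D", "D"] <- 1
  structure(M, strategy = strategy, rescaled = rescaled)
}

# horizon end age under the configured over-84 rule
.effective_max_age <- function(cfg) {
  if (cfg$over_84_rule == "truncate") min(cfg$max_age, 85L) else cfg$max_age
}

#' Run the lifetime cohort trace
#'
#' Starts the whole cohort in Resolved ACS at \code{cfg$start_age} and
#' applies the age-appropriate transition matrix each one-year cycle until
#' \code{cfg$max_age} (or age 85 under \code{over_84_rule = "truncate"}).
#' State occupancies are tracked as exact proportions of a cohort of
#' measure 1.
#'
#' @inheritParams transition_matrix
#' @return An object of class \code{acs_trace}: a data frame with columns
#'   \code{cycle}, \code{age}, \code{RA}, \code{MI}, \code{CAr}, \code{Rv},
#'   \code{D}; attributes \code{strategy} and \code{rescaled} (number of
#'   row-rescaling events across all matrices used).
#' @examples
#' tr <- run_cohort(acs_parameters(), "LMIS")
#' head(tr, 3)
#' @export
run_cohort <- function(p, strategy = .STRATEGIES, cfg = model_config()) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(cfg, "acs_config"))
  ep <- .engine_params(p)
  .run_cohort_ep(ep, strategy, cfg)
}

.run_cohort_ep <- function(ep, strategy, cfg) {
  end_age <- .effective_max_age(cfg)
  n_cyc <- end_age - cfg$start_age          # transitions; cycles 0..n_cyc
  occ <- matrix(0, n_cyc + 1L, 5L, dimnames = list(NULL, .STATES))
  occ[1L, "RA"] <- 1
  rescaled <- 0L
  if (n_cyc > 0L) {
    ages <- cfg$start_age + 0:(n_cyc - 1L)
    bands <- .band_index(ages, cfg$over_84_rule)
    mats <- vector("list", 11L)
    for (t in seq_len(n_cyc)) {
      b <- bands[t]
      if (is.null(mats[[b]])) {
        mats[[b]] <- .build_matrix(ep, strategy, b, cfg)
        rescaled <- rescaled + attr(mats[[b]], "rescaled")
      }
      occ[t + 1L, ] <- occ[t, ] %*% mats[[b]]
    }
  }
  out <- data.frame(cycle = 0:n_cyc, age = cfg$start_age + 0:n_cyc)
  out <- cbind(out, as.data.frame(occ))
  structure(out, strategy = strategy, rescaled = rescaled,
            class = c("acs_trace", "data.frame"))
}

#' @export
print.acs_trace <- function(x, ...) {
  cat(sprintf("Cohort trace (%s): %d cycles, ages %d-%d\n",
              attr(x, "strategy"), nrow(x) - 1L, x$age[1], x$age[nrow(x)]))
  cat(sprintf("  final state occupancy: alive %.4f, dead %.4f\n",
              1 - x$D[nrow(x)], x$D[nrow(x)]))
  invisible(x)
}
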