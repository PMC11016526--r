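# Economics layer: discounting, per-cycle accrual of costs and QALYs, and
# incremental cost-effectiveness statistics.

#' Discount factor
#'
#' End-of-cycle discounting: cycle 0 is undiscounted and cycle \eqn{t}
#' receives weight \eqn{1/(1+r)^t}.
#'
#' @param rate annual discount rate (>= 0).
#' @param cycle cycle index (integer >= 0, vectorized).
#' @return Numeric discount factor(s).
#' @examples
#' discount_factor(0.03, 0:2)
#' @export
discount_factor <- function(rate, cycle) {
  if (!is.finite(rate) || rate < 0) stop("rate must be nonnegative")
  if (any(cycle < 0)) stop("cycle must be nonnegative")
  1 / (1 + rate)^cycle
}

#' Accrue discounted costs and QALYs over a cohort trace
#'
#' Per cycle, the state cost is the occupancy-weighted sum of the per-state
#' direct medical costs (Death costs nothing), the drug cost is the annual
#' statin cost of the strategy accrued by every alive patient, and the QALY
#' accrual is the occupancy-weighted sum of the state utilities (Death has
#' utility 0). Costs are discounted at the cost rate and QALYs at the
#' outcome rate; with \code{cfg$half_cycle_correction} the first and last
#' cycles carry half weight.
#'
#' @param trace \code{acs_trace} from \code{\link{run_cohort}}.
#' @param p parameter set used to produce the trace.
#' @param strategy \code{"HIS"} or \code{"LMIS"}; defaults to the trace's
#'   own strategy.
#' @param cfg model configuration.
#' @return Object of class \code{acs_result}: list with \code{strategy},
#'   \code{total_cost}, \code{total_qaly}, \code{life_years} (all
#'   discounted), \code{drug_cost} (discounted lifetime drug cost) and the
#'   \code{per_cycle} accrual table.
#' @export
accumulate <- function(trace, p, strategy = NULL, cfg = model_config()) {
  stopifnot(inherits(trace, "acs_trace"), inherits(cfg, "acs_config"))
  if (is.null(strategy)) strategy <- attr(trace, "strategy")
  strategy <- match.arg(strategy, .STRATEGIES)
  ep <- .engine_params(p)
  .accumulate_ep(trace, ep, strategy, cfg)
}

.accumulate_ep <- function(trace, ep, strategy, cfg) {
  occ <- as.matrix(trace[, .STATES])
  cyc <- trace$cycle
  drC <- if (!is.null(cfg$discount_cost)) cfg$discount_cost else ep$dr[1]
  drO <- if (!is.null(cfg$discount_outcome)) cfg$discount_outcome else ep$dr[2]
  dfC <- discount_factor(drC, cyc)
  dfO <- discount_factor(drO, cyc)
  w <- rep(1, length(cyc))
  if (cfg$half_cycle_correction && length(cyc) > 1L) {
    w[1L] <- 0.5
    w[length(cyc)] <- 0.5
  }
  alive <- 1 - occ[, "D"]
  annual_drug <- if (strategy == "HIS") ep$drug[1] else ep$drug[2]
  state_cost <- as.numeric(occ %*% ep$dmc)
  drug_cost <- alive * annual_drug
  qaly <- as.numeric(occ %*% ep$u)
  per_cycle <- data.frame(
    cycle = cyc, age = trace$age,
    state_cost = state_cost, drug_cost = drug_cost, qaly = qaly,
    disc_cost = w * dfC * (state_cost + drug_cost),
    disc_qaly = w * dfO * qaly
  )
  structure(list(
    strategy = strategy,
    total_cost = sum(per_cycle$disc_cost),
    total_qaly = sum(per_cycle$disc_qaly),
    life_years = sum(w * dfO * alive),
    drug_cost = sum(w * dfC * drug_cost),
    per_cycle = per_cycle
  ), class = "acs_result")
}

#' @export
print.acs_result <- function(x, ...) {
  cat(sprintf("%s strategy (discounted, per patient):\n", x$strategy))
  cat(sprintf("  total cost  %s IDR (drug %s IDR)\n",
              format(round(x$total_cost, 2), big.mark = ",", scientific = FALSE),
              format(round(x$drug_cost, 2), big.mark = ",", scientific = FALSE)))
  cat(sprintf("  total QALYs %.4f over %.4f discounted life-years\n",
              x$total_qaly, x$life_years))
  invisible(x)
}

#' Incremental cost-effectiveness ratio
#'
#' Computes the incremental result of an intervention against a comparator:
#' \eqn{\Delta C / \Delta Q}. When the QALY difference is numerically zero
#' the ratio is flagged \code{"undefined"}; an intervention that saves money
#' and gains QALYs is \code{"dominant"}, one that costs more and loses QALYs
#' is \code{"dominated"}.
#'
#' @param intervention,comparator \code{acs_result} objects from the same
#'   configuration.
#' @return Object of class \code{acs_icer}: list with \code{delta_cost},
#'   \code{delta_qaly}, \code{icer} (numeric or \code{NA} when flagged),
#'   \code{flag} (\code{"ratio"}, \code{"dominant"}, \code{"dominated"},
#'   \code{"undefined"}) and the cost-effectiveness-plane \code{quadrant}
#'   (\code{"NE"}, \code{"NW"}, \code{"SE"}, \code{"SW"}).
#' @export
icer <- function(intervention, comparator) {
  stopifnot(inherits(intervention, "acs_result"),
            inherits(comparator, "acs_result"))
  dc <- intervention$total_cost - comparator$total_cost
  dq <- intervention$total_qaly - comparator$total_qaly
  quadrant <- paste0(if (dc >= 0) "N" else "S", if (dq >= 0) "E" else "W")
  if (abs(dq) < 1e-12) {
    flag <- "undefined"; ic <- NA_real_
  } else {
    ic <- dc / dq
    flag <- if (dc < 0 && dq > 0) "dominant"
            else if (dc > 0 && dq < 0) "dominated"
            else "ratio"
  }
  structure(list(
    intervention = intervention$strategy,
    comparator = comparator$strategy,
    delta_cost = dc, delta_qaly = dq,
    icer = ic, flag = flag, quadrant = quadrant
  ), class = "acs_icer")
}

#' @export
print.acs_icer <- function(x, ...) {
  cat(sprintf("%s vs %s: dCost = %s IDR, dQALY = %.6f\n",
              x$intervention, x$comparator,
              format(round(x$delta_cost, 2), big.mark = ",",
                     scientific = FALSE), x$delta_qaly))
  if (x$flag == "ratio")
    cat(sprintf("  ICER = %s IDR per QALY (quadrant %s)\n",
                format(round(x$icer, 2), big.mark = ",", scientific = FALSE),
                x$quadrant))
  else
    cat(sprintf("  %s (quadrant %s)\n", x$flag, x$quadrant))
  invisible(x)
}

#' Net monetary benefit
#'
#' \eqn{NMB = WTP \cdot QALY - Cost}. The intervention is cost-effective at
#' a threshold exactly when its incremental NMB against the comparator is
#' positive.
#'
#' @param result \code{acs_result}.
#' @param wtp willingness-to-pay threshold(s), IDR per QALY (>= 0).
#' @return Numeric NMB in IDR, one value per threshold.
#' @export
net_monetary_benefit <- function(result, wtp) {
  stopifnot(inherits(result, "acs_result"))
  if (any(!is.finite(wtp)) || any(wtp < 0))
    stop("wtp must be nonnegative")
  wtp * result$total_qaly - result$total_cost
}
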