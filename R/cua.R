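# Main entry: deterministic base-case cost-utility analysis comparing the
# two statin strategies, returned as one classed object.

#' Cost-utility analysis of high- vs low-to-moderate-intensity statins
#'
#' Runs the lifetime Markov cohort model once per strategy with the
#' parameter-table means (the deterministic base case), accrues discounted
#' costs and QALYs, and computes the incremental cost-effectiveness ratio of
#' high-intensity statin (HIS) therapy against low-to-moderate-intensity
#' statin (LMIS) therapy.
#'
#' @param params parameter table (\code{acs_parameters}); defaults to the
#'   packaged reference table.
#' @param config model configuration (\code{acs_config}).
#' @param ... convenience overrides forwarded to \code{\link{model_config}}
#'   when \code{config} is left at its default.
#' @param validate if \code{TRUE} (default) reject invalid parameter tables;
#'   sensitivity analyses that push single parameters beyond joint
#'   feasibility (the engine then rescales rows) set this to \code{FALSE}.
#' @return Object of class \code{acs_cua}: list with the inputs, the two
#'   cohort \code{traces}, the per-strategy \code{results}, the
#'   \code{incremental} record, and \code{rescaled} (count of transition
#'   rows rescaled for feasibility, normally 0 for the reference table).
#'   Methods: \code{print}, \code{summary}, \code{plot} (occupancy traces),
#'   \code{simulate} (probabilistic sensitivity analysis, see
#'   \code{\link{run_psa}}).
#' @examples
#' fit <- acs_cua()
#' fit
#' summary(fit)
#' @export
acs_cua <- function(params = acs_parameters(), config = NULL, ...,
                    validate = TRUE) {
  if (is.null(config)) config <- model_config(...)
  stopifnot(inherits(config, "acs_config"))
  if (validate) {
    v <- validate_parameters(params)
    if (nrow(v))
      stop("invalid parameter set:\n",
           paste0("  ", v$symbol, ": ", v$message, collapse = "\n"))
  }
  ep <- .engine_params(params)
  traces <- results <- list()
  rescaled <- 0L
  for (s in .STRATEGIES) {
    tr <- .run_cohort_ep(ep, s, config)
    rescaled <- rescaled + attr(tr, "rescaled")
    traces[[s]] <- tr
    results[[s]] <- .accumulate_ep(tr, ep, s, config)
  }
  structure(list(
    params = params,
    config = config,
    traces = traces,
    results = results,
    incremental = icer(results$HIS, results$LMIS),
    rescaled = rescaled
  ), class = "acs_cua")
}

#' @export
print.acs_cua <- function(x, ...) {
  cat("Lifetime Markov cost-utility analysis: HIS vs LMIS\n")
  cat(sprintf("  cohort entering at age %d, horizon age %d, discounting %s%%/%s%% (cost/outcome)\n",
              x$config$start_age, x$config$max_age,
              format(100 * .effective_rates(x)[1]),
              format(100 * .effective_rates(x)[2])))
  for (s in .STRATEGIES) {
    r <- x$results[[s]]
    cat(sprintf("  %-4s cost %18s IDR   QALYs %8.4f\n", s,
                format(round(r$total_cost, 2), big.mark = ",",
                       scientific = FALSE), r$total_qaly))
  }
  inc <- x$incremental
  if (inc$flag == "ratio")
    cat(sprintf("  ICER %18s IDR per QALY\n",
                format(round(inc$icer, 2), big.mark = ",",
                       scientific = FALSE)))
  else cat("  incremental result:", inc$flag, "\n")
  invisible(x)
}

.effective_rates <- function(x) {
  ep <- .engine_params(x$params)
  c(if (!is.null(x$config$discount_cost)) x$config$discount_cost else ep$dr[1],
    if (!is.null(x$config$discount_outcome)) x$config$discount_outcome
    else ep$dr[2])
}

#' @export
summary.acs_cua <- function(object, wtp = object$config$wtp, ...) {
  inc <- object$incremental
  tab <- data.frame(
    strategy = .STRATEGIES,
    total_cost = vapply(object$results, function(r) r$total_cost, 0),
    drug_cost = vapply(object$results, function(r) r$drug_cost, 0),
    total_qaly = vapply(object$results, function(r) r$total_qaly, 0),
    life_years = vapply(object$results, function(r) r$life_years, 0),
    row.names = NULL
  )
  inmb <- wtp * inc$delta_qaly - inc$delta_cost
  structure(list(
    strategies = tab,
    incremental = inc,
    wtp = wtp,
    inmb = inmb,
    cost_effective = inmb > 0,
    cohort_size = object$config$cohort_size,
    rescaled = object$rescaled
  ), class = "summary.acs_cua")
}

#' @export
print.summary.acs_cua <- function(x, ...) {
  cat("Per-patient discounted totals:\n")
  tab <- x$strategies
  tab$total_cost <- format(round(tab$total_cost, 2), big.mark = ",",
                           scientific = FALSE)
  tab$drug_cost <- format(round(tab$drug_cost, 2), big.mark = ",",
                          scientific = FALSE)
  print(tab, row.names = FALSE)
  print(x$incremental)
  for (i in seq_along(x$wtp))
    cat(sprintf("  at WTP %s IDR/QALY: incremental NMB %s IDR (%scost-effective)\n",
                format(x$wtp[i], big.mark = ",", scientific = FALSE),
                format(round(x$inmb[i], 2), big.mark = ",",
                       scientific = FALSE),
                if (x$cost_effective[i]) "" else "not "))
  if (x$rescaled > 0)
    cat("  note:", x$rescaled, "transition row(s) rescaled for feasibility\n")
  invisible(x)
}

#' @export
plot.acs_cua <- function(x, states = c("RA", "MI", "CAr", "Rv", "D"), ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (s in .STRATEGIES) {
    tr <- x$traces[[s]]
    graphics::matplot(tr$age, as.matrix(tr[, states]), type = "l", lty = 1,
                      xlab = "age (years)", ylab = "state occupancy",
                      main = s, ylim = c(0, 1), ...)
    graphics::legend("right", legend = states, col = seq_along(states),
                     lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis as simulation from a fitted analysis
#'
#' \code{simulate()} on an \code{acs_cua} object re-runs the analysis
#' \code{nsim} times with parameter tables drawn from their uncertainty
#' distributions; it is a convenience wrapper around \code{\link{run_psa}}.
#'
#' @param object \code{acs_cua} object.
#' @param nsim number of Monte Carlo iterations.
#' @param seed integer seed controlling all sampling.
#' @param ... unused.
#' @return An \code{acs_psa} object, see \code{\link{run_psa}}.
#' @export
simulate.acs_cua <- function(object, nsim = 1000, seed = 1L, ...) {
  run_psa(object$params, object$config, n = nsim, seed = seed)
}
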