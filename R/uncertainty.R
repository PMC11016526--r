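# Probabilistic sensitivity analysis: method-of-moments parameter sampling,
# Monte Carlo propagation, acceptability curves, and the CE-plane table.

# method-of-moments parameterisations ----------------------------------------

.mom_beta <- function(m, s) {
  # requires s^2 < m(1-m); validated upstream
  nu <- m * (1 - m) / s^2 - 1
  c(shape1 = m * nu, shape2 = (1 - m) * nu)
}

.mom_gamma <- function(m, s) c(shape = m^2 / s^2, rate = m / s^2)

.mom_lnorm <- function(m, s) {
  # mean and sd on the natural scale
  sigma2 <- log(1 + s^2 / m^2)
  c(meanlog = log(m) - sigma2 / 2, sdlog = sqrt(sigma2))
}

# one random draw for a single parameter row; se of 0/NA is degenerate
.draw_param <- function(mean, se, family) {
  if (is.na(se) || se == 0) return(mean)
  switch(family,
    probability = ,
    utility = {
      if (mean <= 0 || mean >= 1) return(mean)
      a <- .mom_beta(mean, se)
      stats::rbeta(1, a[1], a[2])
    },
    cost = {
      if (mean <= 0) return(mean)
      g <- .mom_gamma(mean, se)
      stats::rgamma(1, shape = g[1], rate = g[2])
    },
    hazard_ratio = {
      l <- .mom_lnorm(mean, se)
      stats::rlnorm(1, l[1], l[2])
    },
    rate = mean  # discount rates are never sampled
  )
}

#' Draw one parameter table from its uncertainty distributions
#'
#' Probabilities and utilities are drawn from beta distributions, costs from
#' gamma distributions, and hazard ratios from lognormal distributions, each
#' parameterised by method of moments from the tabulated mean and standard
#' error. Parameters without a standard error (and the discount rates) stay
#' at their means. The Resolved-ACS stay probability is set to the residual
#' \eqn{1 - (tpRA\_MI + tpRA\_CAr + tpRA\_Rv)} so the row remains
#' stochastic; if a sampled row's listed outgoing mass exceeds 1 it is
#' rescaled proportionally (the count is recorded in the \code{"rescaled"}
#' attribute).
#'
#' Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param p base parameter table.
#' @param max_attempts resample attempts before giving up when a draw fails
#'   validation.
#' @return A validated \code{acs_parameters} object with attributes
#'   \code{rescaled} (rows rescaled) and \code{resampled} (extra attempts
#'   used).
#' @export
sample_parameters <- function(p, max_attempts = 100L) {
  stopifnot(inherits(p, "acs_parameters"))
  base <- as.data.frame(p)
  fixed <- c("drC", "drO", "tpRA_RA")
  for (attempt in seq_len(max_attempts)) {
    tab <- base
    rescaled <- 0L
    for (i in seq_len(nrow(tab))) {
      if (tab$name[i] %in% fixed) next
      tab$mean[i] <- .draw_param(base$mean[i], base$se[i], base$family[i])
    }
    g <- function(nm) tab$mean[match(nm, tab$name)]
    setv <- function(nm, v) tab$mean[match(nm, tab$name)] <<- v
    # Resolved-ACS row: stay probability is the residual
    ev <- g(c("tpRA_MI", "tpRA_CAr", "tpRA_Rv"))
    if (sum(ev) > 1) {
      ev <- ev / sum(ev)
      rescaled <- rescaled + 1L
      setv(c("tpRA_MI", "tpRA_CAr", "tpRA_Rv"), ev)
    }
    setv("tpRA_RA", 1 - sum(ev))
    # event rows must stay feasible in their worst age band
    for (st in c("MI", "Rv")) {
      syms <- c(paste0("tp", st, "_", st),
                if (st == "MI") "tpMI_Rv" else "tpRv_MI")
      worst <- max(g(.mortality_symbols(st)))
      tot <- sum(g(syms)) + worst
      if (tot > 1) {
        # scale the whole row (stay, cross-event, all death bands)
        f <- 1 / tot
        setv(syms, g(syms) * f)
        setv(.mortality_symbols(st), g(.mortality_symbols(st)) * f)
        rescaled <- rescaled + 1L
      }
    }
    out <- as_acs_parameters(tab, check = FALSE)
    if (nrow(validate_parameters(out)) == 0L) {
      attr(out, "rescaled") <- rescaled
      attr(out, "resampled") <- attempt - 1L
      return(out)
    }
  }
  stop("failed to draw a valid parameter set in ", max_attempts, " attempts")
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: each iteration draws
#' one parameter table (\code{\link{sample_parameters}}), runs both
#' strategies through the Markov engine under the same draw (common random
#' parameters, so the hazard ratios are the only between-arm difference),
#' and records discounted totals and increments. Iteration \eqn{i}'s draws
#' are a deterministic function of \code{(seed, i)}, so runs are exactly
#' reproducible.
#'
#' @param p base parameter table.
#' @param cfg model configuration.
#' @param n number of iterations.
#' @param seed integer seed.
#' @return Object of class \code{acs_psa}: a data frame with one row per
#'   iteration (\code{iteration}, \code{cost_HIS}, \code{qaly_HIS},
#'   \code{cost_LMIS}, \code{qaly_LMIS}, \code{delta_cost},
#'   \code{delta_qaly}) and attributes \code{seed}, \code{wtp},
#'   \code{rescaled}, \code{resampled}, \code{base_icer}.
#' @examples
#' psa <- run_psa(acs_parameters(), n = 25, seed = 1)
#' summary(psa)
#' @export
run_psa <- function(p, cfg = model_config(), n = 1000, seed = 1L) {
  stopifnot(inherits(cfg, "acs_config"), n >= 1)
  v <- validate_parameters(p)
  if (nrow(v))
    stop("invalid parameter set:\n",
         paste0("  ", v$symbol, ": ", v$message, collapse = "\n"))
  # an absent SE on a sampled parameter is an input defect (se = 0 is the
  # legitimate way to pin a parameter at its mean)
  sampled <- p$family != "rate" & p$name != "tpRA_RA"
  no_se <- p$name[sampled & is.na(p$se)]
  if (length(no_se))
    stop("parameters lack standard errors for sampling: ",
         paste(no_se, collapse = ", "))
  iter_seeds <- .with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  rows <- vector("list", n)
  rescaled <- resampled <- 0L
  for (i in seq_len(n)) {
    ps <- .with_seed(iter_seeds[i], sample_parameters(p))
    rescaled <- rescaled + attr(ps, "rescaled")
    resampled <- resampled + attr(ps, "resampled")
    ep <- .engine_params(ps)
    res <- lapply(.STRATEGIES, function(s)
      .accumulate_ep(.run_cohort_ep(ep, s, cfg), ep, s, cfg))
    rows[[i]] <- c(res[[1]]$total_cost, res[[1]]$total_qaly,
                   res[[2]]$total_cost, res[[2]]$total_qaly)
  }
  m <- do.call(rbind, rows)
  out <- data.frame(
    iteration = seq_len(n),
    cost_HIS = m[, 1], qaly_HIS = m[, 2],
    cost_LMIS = m[, 3], qaly_LMIS = m[, 4],
    delta_cost = m[, 1] - m[, 3],
    delta_qaly = m[, 2] - m[, 4]
  )
  base <- acs_cua(params = p, config = cfg)
  structure(out, seed = seed, wtp = cfg$wtp, rescaled = rescaled,
            resampled = resampled, base_icer = base$incremental$icer,
            class = c("acs_psa", "data.frame"))
}

#' @export
print.acs_psa <- function(x, ...) {
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %s)\n",
              nrow(x), format(attr(x, "seed"))))
  s <- summary(x)
  cat(sprintf("  mean dCost %s IDR, mean dQALY %.6f\n",
              format(round(s$mean_delta_cost, 2), big.mark = ",",
                     scientific = FALSE), s$mean_delta_qaly))
  cat(sprintf("  probabilistic ICER (ratio of means) %s IDR/QALY\n",
              format(round(s$icer_ratio_of_means, 2), big.mark = ",",
                     scientific = FALSE)))
  invisible(x)
}

#' @export
summary.acs_psa <- function(object, wtp = attr(object, "wtp"), ...) {
  ratios <- object$delta_cost / object$delta_qaly
  structure(list(
    n = nrow(object),
    mean_delta_cost = mean(object$delta_cost),
    mean_delta_qaly = mean(object$delta_qaly),
    icer_ratio_of_means = mean(object$delta_cost) / mean(object$delta_qaly),
    icer_median_of_ratios = stats::median(ratios[is.finite(ratios)]),
    prob_qaly_gain = mean(object$delta_qaly > 0),
    quadrants = table(paste0(ifelse(object$delta_cost >= 0, "N", "S"),
                             ifelse(object$delta_qaly >= 0, "E", "W"))),
    ceac = ceac(object, wtp),
    rescaled = attr(object, "rescaled"),
    resampled = attr(object, "resampled")
  ), class = "summary.acs_psa")
}

#' @export
print.summary.acs_psa <- function(x, ...) {
  cat(sprintf("PSA over %d iterations\n", x$n))
  cat(sprintf("  probabilistic ICER: ratio of means %s, median of ratios %s IDR/QALY\n",
              format(round(x$icer_ratio_of_means, 2), big.mark = ",",
                     scientific = FALSE),
              format(round(x$icer_median_of_ratios, 2), big.mark = ",",
                     scientific = FALSE)))
  cat(sprintf("  P(QALY gain) = %.3f; quadrants: %s\n", x$prob_qaly_gain,
              paste(names(x$quadrants), x$quadrants, sep = "=",
                    collapse = ", ")))
  cat("  probability cost-effective:\n")
  for (i in seq_len(nrow(x$ceac)))
    cat(sprintf("    WTP %s IDR/QALY: %.3f\n",
                format(x$ceac$wtp[i], big.mark = ",", scientific = FALSE),
                x$ceac$probability[i]))
  if (x$resampled > 0 || x$rescaled > 0)
    cat(sprintf("  feasibility: %d row(s) rescaled, %d redraw(s)\n",
                x$rescaled, x$resampled))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which the intervention has positive incremental net monetary benefit,
#' \eqn{WTP \cdot \Delta Q - \Delta C > 0}.
#'
#' @param psa \code{acs_psa} object.
#' @param wtp vector of thresholds (IDR per QALY); defaults to the run's
#'   configured thresholds.
#' @return Data frame with columns \code{wtp} and \code{probability}.
#' @export
ceac <- function(psa, wtp = attr(psa, "wtp")) {
  stopifnot(inherits(psa, "acs_psa"))
  if (nrow(psa) == 0L) stop("empty PSA iteration set")
  wtp <- sort(as.numeric(wtp))
  prob <- vapply(wtp, function(l)
    mean(l * psa$delta_qaly - psa$delta_cost > 0), 0)
  data.frame(wtp = wtp, probability = prob)
}

#' Cost-effectiveness plane table
#'
#' One row per PSA iteration with the incremental effectiveness and cost;
#' the configured willingness-to-pay thresholds are attached as the
#' \code{"wtp"} attribute for ceiling-line rendering.
#'
#' @param psa \code{acs_psa} object.
#' @return Data frame with columns \code{iteration}, \code{delta_qaly},
#'   \code{delta_cost}.
#' @export
ce_plane <- function(psa) {
  stopifnot(inherits(psa, "acs_psa"))
  if (nrow(psa) == 0L) stop("empty PSA iteration set")
  structure(data.frame(iteration = psa$iteration,
                       delta_qaly = psa$delta_qaly,
                       delta_cost = psa$delta_cost),
            wtp = attr(psa, "wtp"))
}

#' @export
plot.acs_psa <- function(x, wtp = attr(x, "wtp"), ...) {
  graphics::plot(x$delta_qaly, x$delta_cost,
                 xlab = "incremental QALYs", ylab = "incremental cost (IDR)",
                 main = "Cost-effectiveness plane", pch = 20,
                 col = grDevices::adjustcolor("steelblue", 0.6), ...)
  graphics::abline(h = 0, v = 0, col = "grey40")
  for (l in wtp) graphics::abline(a = 0, b = l, lty = 2)
  invisible(x)
}
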