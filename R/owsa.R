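# One-way deterministic sensitivity analysis (tornado diagram data).

#' One-way (tornado) sensitivity analysis
#'
#' Recomputes the deterministic ICER with each parameter in turn set to a
#' low and a high bound, all other parameters held at base case. Under
#' \code{range_rule = "ci95"} the bounds are mean +/- 1.96 standard errors,
#' clipped to the parameter's domain (probabilities and utilities to
#' \eqn{[0,1]}, costs and hazard ratios to nonnegative values); under
#' \code{"pct20"} they are mean +/- 20\%. Parameters without a standard
#' error are skipped under \code{"ci95"}, except the two discount rates,
#' which are always varied over the guideline interval [0, 0.05]. The
#' Resolved-ACS stay probability is the model's row residual, so varying it
#' has no effect and it is reported with zero spread.
#'
#' @param p parameter table.
#' @param cfg model configuration.
#' @param range_rule \code{"ci95"} or \code{"pct20"}.
#' @return Object of class \code{acs_owsa}: data frame with one row per
#'   varied parameter (\code{parameter}, \code{low_value},
#'   \code{high_value}, \code{icer_low}, \code{icer_high}, \code{spread}),
#'   sorted by decreasing spread; attribute \code{base_icer}.
#' @examples
#' tor <- owsa(acs_parameters())
#' head(tor, 3)
#' @export
owsa <- function(p, cfg = model_config(), range_rule = c("ci95", "pct20")) {
  range_rule <- match.arg(range_rule)
  stopifnot(inherits(p, "acs_parameters"), inherits(cfg, "acs_config"))
  base <- acs_cua(params = p, config = cfg)
  base_icer <- base$incremental$icer

  clip <- function(v, family) {
    switch(family,
      probability = , utility = pmin(pmax(v, 0), 1),
      cost = pmax(v, 0),
      hazard_ratio = pmax(v, 1e-12),
      rate = pmax(v, 0))
  }
  icer_at <- function(name, value) {
    q <- as.data.frame(p)
    i <- match(name, q$name)
    if (q$family[i] == "rate") {
      # discount-rate overrides bypass the table so both readings agree
      cfg2 <- cfg
      if (name == "drC") cfg2$discount_cost <- value
      if (name == "drO") cfg2$discount_outcome <- value
      q$mean[i] <- value
      fit <- acs_cua(params = as_acs_parameters(q, check = FALSE),
                     config = cfg2, validate = FALSE)
    } else {
      q$mean[i] <- value
      fit <- acs_cua(params = as_acs_parameters(q, check = FALSE),
                     config = cfg, validate = FALSE)
    }
    fit$incremental$icer
  }

  rows <- list()
  for (i in seq_len(nrow(p))) {
    nm <- p$name[i]; m <- p$mean[i]; s <- p$se[i]; fam <- p$family[i]
    if (fam == "rate") {
      lo <- 0; hi <- 0.05
    } else if (range_rule == "ci95") {
      if (is.na(s) || s == 0) next
      lo <- clip(m - 1.96 * s, fam); hi <- clip(m + 1.96 * s, fam)
    } else {
      lo <- clip(m * 0.8, fam); hi <- clip(m * 1.2, fam)
    }
    il <- icer_at(nm, lo); ih <- icer_at(nm, hi)
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = nm, low_value = lo, high_value = hi,
      icer_low = il, icer_high = ih, spread = abs(ih - il),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread, out$parameter), ]
  rownames(out) <- NULL
  structure(out, base_icer = base_icer, range_rule = range_rule,
            class = c("acs_owsa", "data.frame"))
}

#' @export
print.acs_owsa <- function(x, n = 10L, ...) {
  cat(sprintf("One-way sensitivity analysis (%s): %d parameters, base ICER %s IDR/QALY\n",
              attr(x, "range_rule"), nrow(x),
              format(round(attr(x, "base_icer"), 2), big.mark = ",",
                     scientific = FALSE)))
  top <- utils::head(as.data.frame(x), n)
  top$spread <- format(round(top$spread), big.mark = ",", scientific = FALSE)
  print(top[, c("parameter", "low_value", "high_value", "spread")],
        row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

#' @export
plot.acs_owsa <- function(x, n = 15L, ...) {
  d <- utils::head(as.data.frame(x), n)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  lo <- pmin(d$icer_low, d$icer_high) - base
  hi <- pmax(d$icer_low, d$icer_high) - base
  old <- graphics::par(mar = c(4, 9, 2, 1))
  on.exit(graphics::par(old))
  graphics::plot(NULL, xlim = range(c(lo, hi, 0)),
                 ylim = c(0.5, nrow(d) + 0.5),
                 yaxt = "n", xlab = "ICER minus base case (IDR/QALY)",
                 ylab = "", main = "Tornado diagram")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$parameter, las = 1,
                 cex.axis = 0.7)
  graphics::rect(lo, seq_len(nrow(d)) - 0.35, hi, seq_len(nrow(d)) + 0.35,
                 col = "steelblue", border = NA)
  graphics::abline(v = 0, col = "grey30")
  invisible(x)
}
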