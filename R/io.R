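# Result serialization, run manifests, and the structural-convention sweep.

#' Sweep the structural conventions of the Markov engine
#'
#' Enumerates the cross-product of the engine's convention switches
#' (residual rule, hazard-ratio transform and scope, half-cycle correction,
#' over-84 rule), recomputes the deterministic ICER for each combination,
#' and, when a reference value is supplied, reports each run's relative
#' deviation from it. Useful when reproducing a published analysis whose
#' conventions are not fully stated.
#'
#' @param p parameter table.
#' @param reference optional reference ICER (IDR per QALY) to compare
#'   against.
#' @param residual_rule,hr_transform,hr_scope,half_cycle_correction,over_84_rule
#'   vectors of values to enumerate; defaults cover the 32 standard
#'   combinations (the exploratory \code{"to_D"} residual rule is opt-in).
#' @param cfg base configuration supplying ages, discounting, and thresholds.
#' @return Object of class \code{acs_sweep}: data frame with one row per
#'   combination (the five switches, \code{delta_cost}, \code{delta_qaly},
#'   \code{icer}, and \code{rel_dev} when a reference is given), sorted by
#'   \code{abs(rel_dev)} when a reference is given.
#' @examples
#' sw <- convention_sweep(acs_parameters(), reference = 3e7)
#' head(sw, 3)
#' @export
convention_sweep <- function(p, reference = NULL,
                             residual_rule = c("to_RA", "stay"),
                             hr_transform = c("multiplicative", "rate_based"),
                             hr_scope = c("all_inbound", "from_RA_only"),
                             half_cycle_correction = c(FALSE, TRUE),
                             over_84_rule = c("hold_last_band", "truncate"),
                             cfg = model_config()) {
  grid <- expand.grid(residual_rule = residual_rule,
                      hr_transform = hr_transform,
                      hr_scope = hr_scope,
                      half_cycle_correction = half_cycle_correction,
                      over_84_rule = over_84_rule,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- model_config(
      start_age = cfg$start_age, max_age = cfg$max_age,
      residual_rule = grid$residual_rule[i],
      hr_transform = grid$hr_transform[i],
      hr_scope = grid$hr_scope[i],
      half_cycle_correction = grid$half_cycle_correction[i],
      over_84_rule = grid$over_84_rule[i],
      discount_cost = cfg$discount_cost,
      discount_outcome = cfg$discount_outcome,
      wtp = cfg$wtp, cohort_size = cfg$cohort_size)
    inc <- acs_cua(params = p, config = cfg_i)$incremental
    data.frame(delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
               icer = inc$icer)
  })
  out <- cbind(grid, do.call(rbind, res))
  if (!is.null(reference)) {
    stopifnot(is.finite(reference), reference != 0)
    out$rel_dev <- out$icer / reference - 1
    out <- out[order(abs(out$rel_dev)), ]
  }
  rownames(out) <- NULL
  structure(out, reference = reference,
            class = c("acs_sweep", "data.frame"))
}

#' @export
print.acs_sweep <- function(x, n = 8L, ...) {
  ref <- attr(x, "reference")
  cat(sprintf("Convention sweep: %d combinations", nrow(x)))
  if (!is.null(ref)) {
    cat(sprintf(", reference ICER %s IDR/QALY\n",
                format(ref, big.mark = ",", scientific = FALSE)))
    best <- x[1L, ]
    cat(sprintf("  closest: %s/%s/%s/hcc=%s/%s at %s (%+.1f%%)\n",
                best$residual_rule, best$hr_transform, best$hr_scope,
                best$half_cycle_correction, best$over_84_rule,
                format(round(best$icer), big.mark = ",", scientific = FALSE),
                100 * best$rel_dev))
  } else cat("\n")
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}

# writers ---------------------------------------------------------------------

.write_manifest <- function(dir, cfg, params_source, seed = NULL,
                            warnings = character()) {
  manifest <- list(
    tool = "acscua",
    version = as.character(utils::packageVersion("acscua")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params_source = params_source,
    seed = seed,
    config = Filter(Negate(is.null), unclass(cfg)),
    warnings = as.character(warnings)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(file.path(dir, "manifest.json"))
}

#' Write base-case results to a directory
#'
#' Writes the per-strategy cohort traces (\code{trace_HIS.csv},
#' \code{trace_LMIS.csv}), per-cycle accrual tables
#' (\code{per_cycle_*.csv}), a structured summary (\code{summary.json})
#' containing totals and the incremental record, and a run manifest
#' (\code{manifest.json}). All numbers use period decimal notation.
#'
#' @param fit \code{acs_cua} object.
#' @param dir output directory, created if needed.
#' @param params_source provenance string recorded in the manifest (e.g. a
#'   file path or \code{"builtin:reference"}).
#' @return The directory, invisibly.
#' @export
write_cua <- function(fit, dir, params_source = "builtin:reference") {
  stopifnot(inherits(fit, "acs_cua"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in .STRATEGIES) {
    utils::write.csv(as.data.frame(fit$traces[[s]]),
                     file.path(dir, paste0("trace_", s, ".csv")),
                     row.names = FALSE)
    utils::write.csv(fit$results[[s]]$per_cycle,
                     file.path(dir, paste0("per_cycle_", s, ".csv")),
                     row.names = FALSE)
  }
  inc <- fit$incremental
  summary <- list(
    strategies = lapply(fit$results, function(r)
      list(total_cost = r$total_cost, total_qaly = r$total_qaly,
           life_years = r$life_years, drug_cost = r$drug_cost)),
    incremental = list(delta_cost = inc$delta_cost,
                       delta_qaly = inc$delta_qaly,
                       icer = inc$icer, flag = inc$flag,
                       quadrant = inc$quadrant)
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  warn <- if (fit$rescaled > 0)
    sprintf("%d transition row(s) rescaled for feasibility", fit$rescaled)
    else character()
  .write_manifest(dir, fit$config, params_source, warnings = warn)
  invisible(dir)
}

#' Write probabilistic sensitivity analysis outputs to a directory
#'
#' Writes the iteration table (\code{psa.csv}), acceptability curve
#' (\code{ceac.csv}), cost-effectiveness-plane table
#' (\code{ce_plane.csv}), a summary with both probabilistic-ICER
#' conventions (\code{psa_summary.json}), and a manifest.
#'
#' @param psa \code{acs_psa} object.
#' @param dir output directory, created if needed.
#' @param cfg configuration used for the run (recorded in the manifest).
#' @param wtp thresholds for the acceptability curve.
#' @param params_source provenance string for the manifest.
#' @return The directory, invisibly.
#' @export
write_psa <- function(psa, dir, cfg = model_config(),
                      wtp = attr(psa, "wtp"),
                      params_source = "builtin:reference") {
  stopifnot(inherits(psa, "acs_psa"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(psa), file.path(dir, "psa.csv"),
                   row.names = FALSE)
  utils::write.csv(ceac(psa, wtp), file.path(dir, "ceac.csv"),
                   row.names = FALSE)
  utils::write.csv(ce_plane(psa), file.path(dir, "ce_plane.csv"),
                   row.names = FALSE)
  s <- summary(psa, wtp = wtp)
  jsonlite::write_json(list(
    n = s$n,
    icer_ratio_of_means = s$icer_ratio_of_means,
    icer_median_of_ratios = s$icer_median_of_ratios,
    mean_delta_cost = s$mean_delta_cost,
    mean_delta_qaly = s$mean_delta_qaly,
    prob_qaly_gain = s$prob_qaly_gain,
    ceac = s$ceac
  ), file.path(dir, "psa_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  warn <- character()
  if (attr(psa, "rescaled") > 0)
    warn <- c(warn, sprintf("%d sampled row(s) rescaled for feasibility",
                            attr(psa, "rescaled")))
  if (attr(psa, "resampled") > 0)
    warn <- c(warn, sprintf("%d infeasible draw(s) resampled",
                            attr(psa, "resampled")))
  .write_manifest(dir, cfg, params_source, seed = attr(psa, "seed"),
                  warnings = warn)
  invisible(dir)
}

#' Write tornado-analysis or convention-sweep tables to a directory
#'
#' @param x \code{acs_owsa} or \code{acs_sweep} object.
#' @param dir output directory, created if needed.
#' @param cfg configuration recorded in the manifest.
#' @param params_source provenance string for the manifest.
#' @return The directory, invisibly.
#' @export
write_table <- function(x, dir, cfg = model_config(),
                        params_source = "builtin:reference") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  file <- if (inherits(x, "acs_owsa")) "tornado.csv"
          else if (inherits(x, "acs_sweep")) "sweep.csv"
          else stop("x must be an acs_owsa or acs_sweep object")
  utils::write.csv(as.data.frame(x), file.path(dir, file), row.names = FALSE)
  .write_manifest(dir, cfg, params_source)
  invisible(dir)
}
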