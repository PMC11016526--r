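# Parameter-table data model: every model input (means, standard errors,
# distribution families) lives in one validated table, the single source of
# truth for a run.

.PARAM_FAMILIES <- c("probability", "cost", "utility", "hazard_ratio", "rate")

.BAND_STARTS <- seq(30L, 80L, by = 5L)
.EVENT_STATES <- c("MI", "CAr", "Rv")
.STATES <- c("RA", "MI", "CAr", "Rv", "D")

# symbols a complete parameter set must declare (mortality bands listed
# programmatically below)
.SCALAR_SYMBOLS <- c(
  "drC", "drO",
  "tpRA_RA", "tpRA_MI", "tpRA_CAr", "tpRA_Rv",
  "tpMI_MI", "tpMI_Rv", "tpRv_Rv", "tpRv_MI",
  "dmcRA", "dmcMI", "dmcCAr", "dmcRv",
  "cHIS", "cNHIS",
  "HR_HIS_MI", "HR_HIS_CAr", "HR_HIS_Rv",
  "uRA", "uMI", "uCAr", "uRv"
)

.mortality_symbols <- function(state) {
  sprintf("tp%s_D_%dto%d", state, .BAND_STARTS, .BAND_STARTS + 4L)
}

.REQUIRED_SYMBOLS <- c(.SCALAR_SYMBOLS,
                       unlist(lapply(.EVENT_STATES, .mortality_symbols)))

#' Reference parameter table for the statin cost-utility model
#'
#' Returns the packaged reference table of model inputs: annual transition
#' probabilities between the five health states (Resolved ACS, Myocardial
#' Infarction, Cardiac Arrest, Revascularization, Death), age-banded
#' event-to-death probabilities in 5-year bands from age 30 to 84, per-state
#' direct medical costs and annual drug costs in Indonesian rupiah (IDR),
#' hazard ratios expressing the relative effect of high-intensity statin
#' therapy on event transitions, per-state utility weights, and 3% annual
#' discount rates for costs and outcomes. Standard errors accompany every
#' sampled quantity and drive the probabilistic sensitivity analysis.
#'
#' @return An object of class \code{acs_parameters}: a data frame with one
#'   row per symbol and columns \code{name}, \code{mean}, \code{se},
#'   \code{family}, \code{age_band_start}, \code{age_band_end},
#'   \code{source}.
#' @examples
#' p <- acs_parameters()
#' subset(p, name == "tpRA_MI")
#' @export
acs_parameters <- function() {
  row <- function(name, mean, se, family, bs = NA_integer_, be = NA_integer_,
                  source = "") {
    data.frame(name = name, mean = mean, se = se, family = family,
               age_band_start = as.integer(bs), age_band_end = as.integer(be),
               source = source, stringsAsFactors = FALSE)
  }
  bands <- function(state, means, ses, source) {
    do.call(rbind, lapply(seq_along(.BAND_STARTS), function(i) {
      row(.mortality_symbols(state)[i], means[i], ses[i], "probability",
          .BAND_STARTS[i], .BAND_STARTS[i] + 4L, source)
    }))
  }
  taylor <- "Taylor et al."
  lin <- "Lin et al."
  inacbg <- "INA-CBGs 2016"
  hosp <- "Indonesia Secondary Hospital Type B"
  tab <- rbind(
    row("drC", 0.03, NA, "rate", source = "WHO 2015"),
    row("drO", 0.03, NA, "rate", source = "WHO 2015"),
    row("tpRA_RA", 0.952, 0.095, "probability", source = ""),
    row("tpRA_MI", 0.012, 0.001, "probability", source = taylor),
    row("tpRA_CAr", 0.001, 0.001, "probability", source = taylor),
    row("tpRA_Rv", 0.035, 0.001, "probability", source = taylor),
    row("tpMI_MI", 0.049, 0.010, "probability", source = taylor),
    row("tpMI_Rv", 0.027, 0.004, "probability", source = taylor),
    bands("MI",
          c(0.007, 0.009, 0.014, 0.020, 0.032, 0.050, 0.084, 0.131, 0.205,
            0.326, 0.508),
          c(0.001, 0.001, 0.001, 0.002, 0.003, 0.005, 0.008, 0.013, 0.021,
            0.033, 0.051), taylor),
    bands("CAr",
          c(0.004, 0.005, 0.008, 0.012, 0.018, 0.028, 0.048, 0.074, 0.116,
            0.185, 0.288),
          c(0.000, 0.001, 0.001, 0.001, 0.002, 0.003, 0.005, 0.007, 0.012,
            0.019, 0.029), taylor),
    row("tpRv_Rv", 0.135, 0.009, "probability", source = taylor),
    row("tpRv_MI", 0.396, 0.024, "probability", source = taylor),
    bands("Rv",
          c(0.004, 0.005, 0.007, 0.011, 0.017, 0.027, 0.045, 0.071, 0.111,
            0.176, 0.274),
          c(0.000, 0.001, 0.001, 0.001, 0.002, 0.003, 0.005, 0.007, 0.011,
            0.018, 0.027), taylor),
    row("dmcRA", 19728100, 197281, "cost", source = inacbg),
    row("dmcMI", 12118800, 121188, "cost", source = inacbg),
    row("dmcCAr", 7041400, 70414, "cost", source = inacbg),
    row("dmcRv", 40024100, 400241, "cost", source = inacbg),
    row("cHIS", 3908568.00, 390856.80, "cost", source = hosp),
    row("cNHIS", 1474656.00, 147465.60, "cost", source = hosp),
    row("HR_HIS_MI", 0.77, 0.07, "hazard_ratio", source = taylor),
    row("HR_HIS_CAr", 1.07, 0.11, "hazard_ratio", source = taylor),
    row("HR_HIS_Rv", 0.73, 0.04, "hazard_ratio", source = taylor),
    row("uRA", 0.78, 0.078, "utility", source = lin),
    row("uMI", 0.65, 0.065, "utility", source = lin),
    row("uCAr", 0.68, 0.068, "utility", source = lin),
    row("uRv", 0.78, 0.078, "utility", source = taylor)
  )
  as_acs_parameters(tab)
}

#' Coerce a data frame to a validated parameter set
#'
#' @param x data frame with columns \code{name}, \code{mean}, \code{se},
#'   \code{family}; optional \code{age_band_start}, \code{age_band_end},
#'   \code{source}.
#' @param check if \code{TRUE} (default) stop with an informative error when
#'   any structural invariant fails.
#' @return \code{acs_parameters} object.
#' @export
as_acs_parameters <- function(x, check = TRUE) {
  stopifnot(is.data.frame(x))
  need <- c("name", "mean", "se", "family")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$age_band_start)) x$age_band_start <- NA_integer_
  if (is.null(x$age_band_end)) x$age_band_end <- NA_integer_
  if (is.null(x$source)) x$source <- ""
  x <- x[, c("name", "mean", "se", "family", "age_band_start",
             "age_band_end", "source")]
  x$name <- as.character(x$name)
  x$mean <- as.numeric(x$mean)
  x$se <- as.numeric(x$se)
  x$family <- as.character(x$family)
  x$age_band_start <- as.integer(x$age_band_start)
  x$age_band_end <- as.integer(x$age_band_end)
  rownames(x) <- NULL
  unknown <- setdiff(x$name, .REQUIRED_SYMBOLS)
  if (length(unknown))
    stop("unknown parameter symbol(s): ", paste(unknown, collapse = ", "))
  absent <- setdiff(.REQUIRED_SYMBOLS, x$name)
  if (length(absent))
    stop("missing parameter symbol(s): ", paste(absent, collapse = ", "))
  if (anyDuplicated(x$name))
    stop("duplicated parameter symbol(s): ",
         paste(unique(x$name[duplicated(x$name)]), collapse = ", "))
  class(x) <- c("acs_parameters", "data.frame")
  if (check) {
    v <- validate_parameters(x)
    if (nrow(v))
      stop("invalid parameter set:\n",
           paste0("  ", v$symbol, ": ", v$message, collapse = "\n"))
  }
  x
}

# fast lookup helpers ---------------------------------------------------------

.pmean <- function(p, name) {
  i <- match(name, p$name)
  if (anyNA(i)) stop("unknown parameter(s): ",
                     paste(name[is.na(i)], collapse = ", "))
  p$mean[i]
}

.pse <- function(p, name) p$se[match(name, p$name)]

# mortality means for one event state, ordered by band (length 11)
.mortality_means <- function(p, state) .pmean(p, .mortality_symbols(state))

#' Validate a parameter set
#'
#' Checks every structural invariant of the model's parameter table:
#' probabilities and utilities in \eqn{[0,1]}, costs nonnegative, hazard
#' ratios positive, beta-feasible standard errors
#' (\eqn{se^2 < m(1-m)}) for probabilities and utilities, complete and
#' contiguous 5-year mortality bands from age 30 to 84 for each event state,
#' and row feasibility of every from-state (listed outgoing probabilities
#' summing to at most 1 in every age band).
#'
#' Violations are returned as data, not raised as errors, so callers (e.g.
#' the probabilistic resampler) can react to them.
#'
#' @param p an \code{acs_parameters} object (or compatible data frame).
#' @return data frame with columns \code{symbol}, \code{constraint},
#'   \code{value}, \code{message}; zero rows when the set is valid.
#' @export
validate_parameters <- function(p) {
  stopifnot(is.data.frame(p))
  out <- list()
  bad <- function(symbol, constraint, value, message) {
    out[[length(out) + 1L]] <<- data.frame(
      symbol = symbol, constraint = constraint, value = value,
      message = message, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(p))) {
    nm <- p$name[i]; m <- p$mean[i]; s <- p$se[i]; fam <- p$family[i]
    if (!fam %in% .PARAM_FAMILIES) {
      bad(nm, "family", NA_real_, paste0("unknown family '", fam, "'"))
      next
    }
    if (!is.finite(m)) {
      bad(nm, "finite_mean", m, "mean is not finite")
      next
    }
    if (fam %in% c("probability", "utility") && (m < 0 || m > 1))
      bad(nm, "unit_interval", m, sprintf("mean %g outside [0, 1]", m))
    if (fam == "cost" && m < 0)
      bad(nm, "nonnegative", m, sprintf("cost mean %g is negative", m))
    if (fam == "hazard_ratio" && m <= 0)
      bad(nm, "positive", m, sprintf("hazard ratio %g is not positive", m))
    if (fam == "rate" && m < 0)
      bad(nm, "nonnegative", m, sprintf("rate %g is negative", m))
    if (!is.na(s) && s < 0)
      bad(nm, "nonnegative_se", s, sprintf("se %g is negative", s))
    if (!is.na(s) && s > 0 && fam %in% c("probability", "utility") &&
        m > 0 && m < 1 && s^2 >= m * (1 - m))
      bad(nm, "beta_feasible", s,
          sprintf("se^2 = %g not below mean*(1-mean) = %g", s^2, m * (1 - m)))
  }
  # mortality band structure
  for (st in .EVENT_STATES) {
    syms <- .mortality_symbols(st)
    idx <- match(syms, p$name)
    if (anyNA(idx)) next  # completeness reported by the constructor
    bs <- p$age_band_start[idx]; be <- p$age_band_end[idx]
    if (!identical(as.integer(bs), .BAND_STARTS) ||
        !identical(as.integer(be), .BAND_STARTS + 4L))
      bad(paste0("tp", st, "_D_*"), "band_structure", NA_real_,
          "bands must be the 11 contiguous 5-year bands 30-34 .. 80-84")
  }
  # row feasibility across bands
  ra <- sum(.pmean(p, c("tpRA_RA", "tpRA_MI", "tpRA_CAr", "tpRA_Rv")))
  if (ra > 1 + 1e-9)
    bad("tpRA_*", "row_sum", ra,
        sprintf("Resolved-ACS row sums to %g > 1", ra))
  for (st in c("MI", "Rv")) {
    stay <- .pmean(p, paste0("tp", st, "_", st))
    other <- if (st == "MI") .pmean(p, "tpMI_Rv") else .pmean(p, "tpRv_MI")
    d <- .mortality_means(p, st)
    tot <- stay + other + d
    if (any(tot > 1 + 1e-9)) {
      b <- which.max(tot)
      bad(paste0("tp", st, "_*"), "row_sum", max(tot),
          sprintf("%s row sums to %g > 1 in band %d-%d", st, max(tot),
                  .BAND_STARTS[b], .BAND_STARTS[b] + 4L))
    }
  }
  if (!length(out))
    return(data.frame(symbol = character(), constraint = character(),
                      value = numeric(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' @export
print.acs_parameters <- function(x, ...) {
  cat("Statin cost-utility model parameter set:", nrow(x), "symbols\n")
  nb <- sum(!is.na(x$age_band_start))
  cat(sprintf("  %d scalar parameters, %d age-banded mortality probabilities\n",
              nrow(x) - nb, nb))
  fams <- table(x$family)
  cat("  families:", paste(names(fams), fams, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

# serialization ----------------------------------------------------------------

#' Read / write a parameter table
#'
#' Two on-disk dialects round-trip exactly: a comma-separated table with
#' columns \code{name}, \code{mean}, \code{se}, \code{family},
#' \code{age_band_start}, \code{age_band_end}, \code{source}, and a YAML
#' mapping of symbol name to the same fields. Numbers always use the period
#' as decimal separator, regardless of locale.
#'
#' @param path file to read or write.
#' @param format \code{"csv"} or \code{"yaml"}; inferred from the file
#'   extension when missing.
#' @return \code{read_parameters} returns a validated
#'   \code{acs_parameters} object; \code{write_parameters} returns
#'   \code{path} invisibly.
#' @export
read_parameters <- function(path, format = c("auto", "csv", "yaml")) {
  format <- .resolve_format(match.arg(format), path)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  } else {
    y <- yaml::read_yaml(path)
    tab <- do.call(rbind, lapply(names(y), function(nm) {
      e <- y[[nm]]
      data.frame(name = nm,
                 mean = as.numeric(e$mean),
                 se = if (is.null(e$se)) NA_real_ else as.numeric(e$se),
                 family = as.character(e$family),
                 age_band_start = if (is.null(e$age_band_start)) NA_integer_
                                  else as.integer(e$age_band_start),
                 age_band_end = if (is.null(e$age_band_end)) NA_integer_
                                else as.integer(e$age_band_end),
                 source = if (is.null(e$source)) "" else as.character(e$source),
                 stringsAsFactors = FALSE)
    }))
  }
  as_acs_parameters(tab)
}

#' @param p parameter set to serialize.
#' @rdname read_parameters
#' @export
write_parameters <- function(p, path, format = c("auto", "csv", "yaml")) {
  format <- .resolve_format(match.arg(format), path)
  stopifnot(inherits(p, "acs_parameters"))
  if (format == "csv") {
    utils::write.csv(as.data.frame(p), path, row.names = FALSE, quote = TRUE)
  } else {
    y <- lapply(seq_len(nrow(p)), function(i) {
      e <- list(mean = p$mean[i], family = p$family[i])
      if (!is.na(p$se[i])) e$se <- p$se[i]
      if (!is.na(p$age_band_start[i])) {
        e$age_band_start <- p$age_band_start[i]
        e$age_band_end <- p$age_band_end[i]
      }
      if (nzchar(p$source[i])) e$source <- p$source[i]
      e
    })
    names(y) <- p$name
    yaml::write_yaml(y, path, precision = 15)
  }
  invisible(path)
}

.resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) "yaml" else "csv"
}
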