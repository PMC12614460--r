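#' Default variable specifications for the ATAAD rupture cohort
#'
#' Returns the per-variable, per-outcome-group summary statistics of the
#' published 774-patient acute type A aortic dissection cohort (47 preoperative
#' ruptures, 727 non-ruptures): median / P25 / P75 per group for the 21
#' continuous variables and exact count / group size for the 13 binary
#' variables. These specifications drive [generate_cohort()], which stands in
#' for the undeposited hospital data.
#'
#' Laboratory variables carry a default missing-completely-at-random rate of
#' 8% (the source data reports under 30% missingness on any laboratory
#' variable); demographics, vitals and history variables are complete.
#'
#' @return A tibble with one row per variable per outcome group and columns
#'   `variable`, `kind` ("continuous" or "binary"), `group` ("non_rupture" or
#'   "rupture"), `median`, `p25`, `p75` (continuous only), `count`, `n_group`
#'   (binary only), `missing_rate`, and `lab` (logical, laboratory variable).
#' @export
#' @examples
#' specs <- default_cohort_specs()
#' dplyr::filter(specs, variable == "egfr")
default_cohort_specs <- function() {
  lab_rate <- 0.08

  # continuous: variable, non-rupture (med, p25, p75), rupture (med, p25, p75), lab
  cont <- tibble::tribble(
    ~variable,        ~m0,    ~q0l,   ~q0u,   ~m1,    ~q1l,  ~q1u,   ~lab,
    "age",            54.00,  46.00,  64.00,  63.00,  53.50, 73.50,  FALSE,
    "sbp",            138.50, 122.00, 157.75, 118.50, 80.00, 129.75, FALSE,
    "dbp",            78.50,  67.25,  91.00,  61.50,  59.25, 77.75,  FALSE,
    "map",            99.15,  94.83,  103.33, 76.00,  63.92, 97.42,  FALSE,
    "lvef",           65.57,  63.00,  67.00,  65.49,  64.35, 65.85,  FALSE,
    "bmi",            25.00,  24.00,  27.00,  25.10,  24.10, 25.60,  FALSE,
    "ph",             7.38,   7.34,   7.41,   7.30,   7.23,  7.34,   TRUE,
    "lactate",        9.00,   2.30,   18.90,  22.00,  4.60,  57.10,  TRUE,
    "pao2",           101.00, 80.41,  132.00, 108.00, 77.90, 148.00, TRUE,
    "oi",             300.14, 239.00, 367.00, 293.00, 210.50, 386.50, TRUE,
    "neutrophil_pct", 0.87,   0.79,   0.90,   0.87,   0.82,  0.91,   TRUE,
    "wbc",            12.87,  9.85,   15.63,  15.44,  13.43, 18.17,  TRUE,
    "rbc",            4.43,   4.04,   4.80,   4.27,   3.88,  4.55,   TRUE,
    "plt",            187.00, 151.50, 227.00, 165.00, 125.00, 201.50, TRUE,
    "tc",             3.35,   0.51,   4.55,   3.02,   0.39,  4.53,   TRUE,
    "creatinine",     69.20,  10.84,  98.20,  92.15,  20.10, 144.00, TRUE,
    "albumin",        33.90,  4.05,   38.60,  28.30,  3.89,  33.90,  TRUE,
    "egfr",           82.38,  61.23,  97.85,  52.52,  35.68, 67.07,  TRUE,
    "d_dimer",        6.98,   2.81,   22.01,  30.40,  14.41, 57.42,  TRUE,
    "alt",            16.50,  3.56,   32.70,  32.74,  10.81, 109.66, TRUE,
    "ast",            22.20,  11.90,  33.95,  39.60,  20.68, 159.82, TRUE
  )

  # binary: variable, non-rupture count (of 727), rupture count (of 47)
  bin <- tibble::tribble(
    ~variable,               ~c0,  ~c1,
    "male",                  575,  30,
    "hypertension_admission", 236, 4,
    "obesity",               295,  5,
    "marfan",                10,   0,
    "hypertension_history",  363,  20,
    "diabetes",              25,   3,
    "cerebrovascular",       36,   5,
    "aortic_insufficiency",  617,  47,
    "cold_extremities",      0,    4,
    "hypoxemia",             10,   0,
    "hematochezia_abd_pain", 7,    0,
    "neurologic_symptoms",   31,   4,
    "syncope",               7,    5
  )

  cont_long <- dplyr::bind_rows(
    dplyr::transmute(cont, variable = .data$variable, kind = "continuous",
                     group = "non_rupture", median = .data$m0, p25 = .data$q0l,
                     p75 = .data$q0u, count = NA_real_, n_group = 727,
                     missing_rate = ifelse(.data$lab, lab_rate, 0),
                     lab = .data$lab),
    dplyr::transmute(cont, variable = .data$variable, kind = "continuous",
                     group = "rupture", median = .data$m1, p25 = .data$q1l,
                     p75 = .data$q1u, count = NA_real_, n_group = 47,
                     missing_rate = ifelse(.data$lab, lab_rate, 0),
                     lab = .data$lab)
  )
  bin_long <- dplyr::bind_rows(
    dplyr::transmute(bin, variable = .data$variable, kind = "binary",
                     group = "non_rupture", median = NA_real_, p25 = NA_real_,
                     p75 = NA_real_, count = .data$c0, n_group = 727,
                     missing_rate = 0, lab = FALSE),
    dplyr::transmute(bin, variable = .data$variable, kind = "binary",
                     group = "rupture", median = NA_real_, p25 = NA_real_,
                     p75 = NA_real_, count = .data$c1, n_group = 47,
                     missing_rate = 0, lab = FALSE)
  )
  specs <- dplyr::bind_rows(cont_long, bin_long)
  specs <- dplyr::arrange(specs, match(.data$variable, c(cont$variable, bin$variable)),
                          .data$group)
  validate_specs(specs)
  specs
}

#' Validate a variable-specification table
#'
#' Checks the structural invariants of a specification tibble as produced by
#' [default_cohort_specs()] or read with [read_specs()]: continuous rows satisfy
#' p25 <= median <= p75; binary rows satisfy 0 <= count <= group size; every
#' missing rate lies in [0, 0.3).
#'
#' @param specs Specification tibble.
#' @return `specs`, invisibly, if valid; otherwise an error.
#' @export
validate_specs <- function(specs) {
  needed <- c("variable", "kind", "group", "median", "p25", "p75",
              "count", "n_group", "missing_rate")
  miss <- setdiff(needed, names(specs))
  if (length(miss)) {
    stop("Specification table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  cont <- specs[specs$kind == "continuous", ]
  if (any(is.na(cont$median) | is.na(cont$p25) | is.na(cont$p75))) {
    stop("Continuous specs must provide median, p25 and p75.", call. = FALSE)
  }
  bad <- cont$p25 > cont$median | cont$median > cont$p75
  if (any(bad)) {
    stop("Quantile ordering violated (need p25 <= median <= p75) for: ",
         paste(unique(cont$variable[bad]), collapse = ", "), call. = FALSE)
  }
  bin <- specs[specs$kind == "binary", ]
  badb <- is.na(bin$count) | bin$count < 0 | bin$count > bin$n_group
  if (any(badb)) {
    stop("Binary counts must satisfy 0 <= count <= group size; violated for: ",
         paste(unique(bin$variable[badb]), collapse = ", "), call. = FALSE)
  }
  if (any(specs$missing_rate < 0 | specs$missing_rate >= 0.3)) {
    stop("Missing rates must lie in [0, 0.3).", call. = FALSE)
  }
  invisible(specs)
}

# Two-piece quantile-matched law -----------------------------------------

# Fit a two-piece (split) distribution to a printed (p25, median, p75)
# triple. On strictly positive support the pieces are log-normal halves
# (right-skew with heavier upper tail when p75 - median > median - p25,
# the typical shape of clinical labs); otherwise plain normal halves.
# All three printed quantiles are matched exactly by construction.
twopiece_fit <- function(median, p25, p75) {
  z75 <- stats::qnorm(0.75)
  if (p25 > 0 && median > 0 && p75 > 0) {
    list(log = TRUE,
         m = log(median),
         s_lo = (log(median) - log(p25)) / z75,
         s_hi = (log(p75) - log(median)) / z75)
  } else {
    list(log = FALSE,
         m = median,
         s_lo = (median - p25) / z75,
         s_hi = (p75 - median) / z75)
  }
}

# Quantile function of the two-piece law; u in (0,1).
twopiece_quantile <- function(u, fit) {
  z <- stats::qnorm(u)
  x <- fit$m + ifelse(u <= 0.5, z * fit$s_lo, z * fit$s_hi)
  if (fit$log) exp(x) else x
}

#' Draw from a calibrated per-group continuous distribution
#'
#' Samples one continuous variable for one outcome group from the two-piece
#' quantile-matched law fitted to the specification's (p25, median, p75)
#' triple. Used to verify calibration: large samples recover the printed
#' quantiles.
#'
#' @param specs Specification tibble (see [default_cohort_specs()]).
#' @param variable Variable name.
#' @param group `"non_rupture"` or `"rupture"`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' x <- sample_group(default_cohort_specs(), "egfr", "rupture", 1000, seed = 1)
#' median(x)
sample_group <- function(specs, variable, group, n, seed = NULL) {
  row <- specs[specs$variable == variable & specs$group == group, ]
  if (nrow(row) != 1L || row$kind != "continuous") {
    stop("No continuous spec for variable '", variable, "' in group '",
         group, "'.", call. = FALSE)
  }
  fit <- twopiece_fit(row$median, row$p25, row$p75)
  draw <- function() twopiece_quantile(stats::runif(n), fit)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Read / write variable specifications as JSON
#'
#' @param specs Specification tibble.
#' @param path File path.
#' @return `read_specs()` returns the specification tibble; `write_specs()`
#'   returns `path` invisibly.
#' @export
write_specs <- function(specs, path) {
  validate_specs(specs)
  jsonlite::write_json(specs, path, dataframe = "rows", na = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_specs
#' @export
read_specs <- function(path) {
  specs <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  specs$lab <- as.logical(specs$lab %||% FALSE)
  validate_specs(specs)
  specs
}
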