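#' Generate a synthetic ATAAD cohort
#'
#' Draws a patient-by-variable table whose group-wise summaries reproduce the
#' variable specifications: exactly `n_event` rupture rows, binary variables
#' allocated to match per-group counts exactly (deterministic allocation, then
#' shuffled within group), and continuous variables drawn per group from the
#' two-piece quantile-matched law so that sample quantiles converge to the
#' printed (p25, median, p75). Optionally imposes a Gaussian-copula rank
#' correlation among continuous variables; by default variables are
#' independent (the source publication gives no covariance information).
#'
#' When `n_total`/`n_event` differ from the specification's group sizes,
#' binary counts are rescaled proportionally (rounded half away from zero).
#'
#' @param specs Specification tibble (default [default_cohort_specs()]).
#' @param n_total Total number of patients (default 774).
#' @param n_event Number of rupture cases (default 47).
#' @param seed Integer seed; the same seed reproduces the cohort bit for bit.
#' @param correlation Optional correlation matrix (Gaussian copula) with
#'   dimnames naming a subset of the continuous variables.
#' @return A tibble with one row per patient, one column per specified
#'   variable, and an integer `rupture` column (0/1) with exactly `n_event`
#'   ones.
#' @export
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(cohort); sum(cohort$rupture)
generate_cohort <- function(specs = default_cohort_specs(), n_total = 774,
                            n_event = 47, seed = 1, correlation = NULL) {
  validate_specs(specs)
  if (n_event < 0 || n_event > n_total) {
    stop("Need 0 <= n_event <= n_total.", call. = FALSE)
  }
  vars <- unique(specs$variable)
  group_sizes <- c(non_rupture = n_total - n_event, rupture = n_event)

  withr::with_seed(seed, {
    parts <- lapply(names(group_sizes), function(g) {
      ng <- group_sizes[[g]]
      cols <- lapply(vars, function(v) {
        row <- specs[specs$variable == v & specs$group == g, ]
        if (row$kind == "continuous") {
          rep(NA_real_, ng)  # filled below (copula path draws jointly)
        } else {
          k <- as.integer(round_half_up(row$count / row$n_group * ng))
          k <- max(0L, min(ng, k))
          # exact allocation then in-group permutation
          vals <- c(rep(1L, k), rep(0L, ng - k))
          vals[sample.int(ng)]
        }
      })
      names(cols) <- vars
      tb <- tibble::as_tibble(cols)

      cont_vars <- unique(specs$variable[specs$kind == "continuous"])
      u <- draw_uniforms(ng, cont_vars, correlation)
      for (v in cont_vars) {
        row <- specs[specs$variable == v & specs$group == g, ]
        fit <- twopiece_fit(row$median, row$p25, row$p75)
        tb[[v]] <- twopiece_quantile(u[, v], fit)
      }
      tb$rupture <- if (g == "rupture") 1L else 0L
      tb
    })
    cohort <- dplyr::bind_rows(parts)
    cohort <- cohort[sample(nrow(cohort)), , drop = FALSE]
  })
  tibble::as_tibble(cohort)
}

# Uniform margins for the continuous block: independent by default, or a
# Gaussian copula over the variables named by `correlation`.
draw_uniforms <- function(n, cont_vars, correlation) {
  u <- matrix(stats::runif(n * length(cont_vars)), nrow = n,
              ncol = length(cont_vars), dimnames = list(NULL, cont_vars))
  if (is.null(correlation)) return(u)
  cv <- rownames(correlation)
  if (is.null(cv) || !all(cv %in% cont_vars)) {
    stop("`correlation` must have dimnames naming continuous variables.",
         call. = FALSE)
  }
  ch <- tryCatch(chol(correlation),
                 error = function(e) stop("`correlation` must be positive definite.",
                                          call. = FALSE))
  z <- matrix(stats::rnorm(n * length(cv)), nrow = n) %*% ch
  u[, cv] <- stats::pnorm(z)
  u
}

#' Inject missing-completely-at-random cells
#'
#' Replaces a per-variable fraction of cells with `NA`, drawn uniformly at
#' random (MCAR), using the `missing_rate` column of the specification table.
#' Exactly `round(rate * n)` cells are masked per variable. The outcome column
#' is never masked, and no row is left fully missing.
#'
#' @param cohort Complete cohort tibble from [generate_cohort()].
#' @param specs Specification tibble whose `missing_rate` column sets the
#'   per-variable rates (all rates must be < 0.3).
#' @param seed Integer seed.
#' @return The cohort with `NA` cells injected.
#' @export
inject_missingness <- function(cohort, specs = default_cohort_specs(), seed = 1) {
  if (anyNA(cohort)) {
    stop("`cohort` must be complete before injecting missingness.", call. = FALSE)
  }
  rates <- specs[!duplicated(specs$variable), c("variable", "missing_rate")]
  if (any(rates$missing_rate >= 0.3)) {
    stop("Missing rates must be below 0.3.", call. = FALSE)
  }
  n <- nrow(cohort)
  withr::with_seed(seed, {
    for (i in seq_len(nrow(rates))) {
      v <- rates$variable[i]
      r <- rates$missing_rate[i]
      if (r <= 0 || !v %in% names(cohort) || identical(v, "rupture")) next
      k <- as.integer(round_half_up(r * n))
      if (k > 0) cohort[[v]][sample(n, k)] <- NA
    }
  })
  cohort
}

#' Read / write a cohort as CSV
#'
#' Plain-text interchange for cohort tables: header row of variable names plus
#' the `rupture` outcome column, missing cells written empty. Writing the same
#' cohort twice produces byte-identical files.
#'
#' @param cohort Cohort tibble.
#' @param path File path.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, na = "", show_col_types = FALSE,
                         progress = FALSE)
  if ("rupture" %in% names(out)) out$rupture <- as.integer(out$rupture)
  out
}
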