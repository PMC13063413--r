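#' Preprocessing configuration
#'
#' Bundles the thresholds of the preprocessing pipeline. Defaults follow the
#' classic conventions where the method leaves them open: Tukey fences with
#' multiplier 1.5, "at least half of the ecosystems" coverage, reference pH 7.
#'
#' @param iqr_multiplier Positive fence multiplier for IQR outlier removal.
#' @param coverage_fraction Fraction of site-experiments a chemical must cover
#'   to be retained, in (0, 1].
#' @param reference_pH Reference pH for the speciation correction.
#' @param apply_ph_correction Correct rate constants to the reference pH?
#' @param apply_dissolved_correction Normalize to the freely dissolved
#'   concentration?
#' @param min_values_for_outlier_test Minimum number of values per chemical
#'   before any outlier is flagged.
#' @param outlier_on_log Flag outliers on log10 k (default) rather than raw k.
#' @return A list with class `preprocess_config`.
#' @export
preprocess_config <- function(iqr_multiplier = 1.5,
                              coverage_fraction = 0.5,
                              reference_pH = 7.0,
                              apply_ph_correction = TRUE,
                              apply_dissolved_correction = TRUE,
                              min_values_for_outlier_test = 4L,
                              outlier_on_log = TRUE) {
  stopifnot(is.numeric(iqr_multiplier), iqr_multiplier > 0,
            is.numeric(coverage_fraction), coverage_fraction > 0,
            coverage_fraction <= 1,
            is.numeric(reference_pH), is.finite(reference_pH),
            min_values_for_outlier_test >= 1)
  structure(list(iqr_multiplier = iqr_multiplier,
                 coverage_fraction = coverage_fraction,
                 reference_pH = reference_pH,
                 apply_ph_correction = isTRUE(apply_ph_correction),
                 apply_dissolved_correction = isTRUE(apply_dissolved_correction),
                 min_values_for_outlier_test = as.integer(min_values_for_outlier_test),
                 outlier_on_log = isTRUE(outlier_on_log)),
            class = "preprocess_config")
}

#' Correct an apparent rate constant for sorption
#'
#' References the rate constant to the freely dissolved concentration of the
#' chemical: sorbed chemical is assumed unavailable to degraders, so the
#' apparent first-order rate constant underestimates the rate constant of the
#' dissolved pool by the dissolved fraction.
#'
#' @param k_apparent Apparent first-order rate constant, 1/day, > 0.
#' @param f_dissolved Fraction freely dissolved, in (0, 1].
#' @return `k_apparent / f_dissolved`.
#' @export
#' @examples
#' dissolved_correct(0.2, 0.5) # 0.4
dissolved_correct <- function(k_apparent, f_dissolved) {
  if (any(!is.finite(k_apparent) | k_apparent <= 0)) {
    stop_rembench("k_apparent must be finite and > 0", "rembench_domain_error")
  }
  if (any(!is.finite(f_dissolved) | f_dissolved <= 0 | f_dissolved > 1)) {
    stop_rembench("f_dissolved must lie in (0, 1]", "rembench_domain_error")
  }
  k_apparent / f_dissolved
}

#' Neutral fraction of a chemical at a given pH
#'
#' Henderson-Hasselbalch speciation under the independent-site approximation:
#' for a monoprotic acid the neutral fraction is 1 / (1 + 10^(pH - pKa)), for
#' a monoprotic base 1 / (1 + 10^(pKa - pH)); multiprotic chemicals take the
#' product of the per-site factors. An empty site list (permanently neutral
#' chemical) gives 1.
#'
#' @param pH Finite pH value.
#' @param pka_sites data.frame with columns `pka` (numeric) and `type`
#'   (`"acid"` or `"base"`), zero rows allowed.
#' @return Neutral fraction in (0, 1].
#' @export
#' @examples
#' neutral_fraction(7, data.frame(pka = 7, type = "acid")) # 0.5
neutral_fraction <- function(pH, pka_sites) {
  if (!is.finite(pH)) {
    stop_rembench("pH must be finite", "rembench_domain_error")
  }
  if (is.null(pka_sites) || nrow(pka_sites) == 0) return(1.0)
  if (!all(pka_sites$type %in% c("acid", "base"))) {
    stop_rembench(
      sprintf("unknown speciation site type(s): %s",
              paste(setdiff(pka_sites$type, c("acid", "base")), collapse = ", ")),
      "rembench_domain_error")
  }
  if (!all(is.finite(pka_sites$pka))) {
    stop_rembench("pKa values must be finite", "rembench_domain_error")
  }
  factors <- ifelse(pka_sites$type == "acid",
                    1 / (1 + 10^(pH - pka_sites$pka)),
                    1 / (1 + 10^(pka_sites$pka - pH)))
  prod(factors)
}

#' Correct a rate constant to a reference pH
#'
#' Assumes only the neutral species is degraded at the measured rate, so the
#' rate constant scales with the neutral fraction:
#' `k_ref = k * f_neutral(reference_pH) / f_neutral(pH_exp)`. The correction
#' is exact for monoprotic chemicals under that assumption and is known to
#' overcorrect to some extent in practice.
#'
#' @param k Rate constant at the experimental pH, 1/day, > 0.
#' @param pH_exp Experimental pH.
#' @param pka_sites Speciation sites as in [neutral_fraction()].
#' @param reference_pH Target pH (default 7).
#' @return Rate constant referenced to `reference_pH`.
#' @export
ph_correct <- function(k, pH_exp, pka_sites, reference_pH = 7.0) {
  if (any(!is.finite(k) | k <= 0)) {
    stop_rembench("k must be finite and > 0", "rembench_domain_error")
  }
  k * neutral_fraction(reference_pH, pka_sites) /
    neutral_fraction(pH_exp, pka_sites)
}

#' Flag outliers in one chemical's values by Tukey fences
#'
#' Quartiles use linear interpolation of order statistics (R's default
#' quantile type 7); values outside `[Q1 - m * IQR, Q3 + m * IQR]` are
#' flagged. With fewer than `min_values` values nothing is flagged. If the
#' IQR is zero, values differing from the median are flagged.
#'
#' @param values Finite numeric vector (missing entries must be removed
#'   before the call); by convention log10 k for one chemical across all
#'   site-experiments.
#' @param multiplier Fence multiplier m (default 1.5).
#' @param min_values Minimum count below which no outlier is declared.
#' @return Logical vector, `TRUE` = outlier.
#' @export
iqr_outlier_mask <- function(values, multiplier = 1.5, min_values = 4L) {
  if (any(!is.finite(values))) {
    stop_rembench("values must be finite (drop missing entries first)",
                  "rembench_domain_error")
  }
  n <- length(values)
  if (n < min_values) return(rep(FALSE, n))
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  if (iqr == 0) return(values != stats::median(values))
  values < q[1] - multiplier * iqr | values > q[2] + multiplier * iqr
}

#' Drop chemicals measured in too few site-experiments
#'
#' Retains chemicals with at least `ceil(coverage_fraction * n_sites)`
#' non-missing values ("at least half of the ecosystems" at the default
#' fraction 0.5). The site list and the order of retained chemicals are
#' unchanged; the operation is idempotent.
#'
#' @param matrix A [rate_matrix()].
#' @param coverage_fraction Required coverage in (0, 1].
#' @return The filtered [rate_matrix()] (possibly with zero chemicals).
#' @export
coverage_filter <- function(matrix, coverage_fraction = 0.5) {
  stopifnot(coverage_fraction > 0, coverage_fraction <= 1)
  need <- ceiling(coverage_fraction * ncol(matrix))
  keep <- rowSums(!is.na(matrix)) >= need
  rate_matrix(matrix[keep, , drop = FALSE])
}

#' Normalize a rate matrix to total organic carbon
#'
#' Subtracts log10 TOC of each site from that site's column, i.e. divides
#' every rate constant by the system's TOC. This is the benchmarking
#' transform with log10 TOC standing in for the benchmark chemical's log
#' rate, and serves as a non-chemical baseline for benchmarking efficacy.
#'
#' @param matrix A [rate_matrix()].
#' @param toc_by_site Named numeric vector, site_id -> TOC (> 0), covering
#'   every site in the matrix.
#' @return A [rate_matrix()] with the same missingness pattern.
#' @export
toc_normalize <- function(matrix, toc_by_site) {
  sites <- colnames(matrix)
  absent <- setdiff(sites, names(toc_by_site))
  if (length(absent) > 0) {
    stop_rembench(sprintf("no TOC value for site(s): %s",
                          paste(absent, collapse = ", ")),
                  "rembench_domain_error")
  }
  toc <- toc_by_site[sites]
  bad <- sites[!is.finite(toc) | toc <= 0]
  if (length(bad) > 0) {
    stop_rembench(sprintf("TOC must be finite and > 0; offending site(s): %s",
                          paste(bad, collapse = ", ")),
                  "rembench_domain_error")
  }
  rate_matrix(sweep(unclass(matrix), 2, log10(toc), `-`))
}

#' Run the full preprocessing pipeline
#'
#' Order of operations: sorption (dissolved-fraction) correction, pH
#' speciation correction, log10 transform and pivot to the chemicals x sites
#' grid, per-chemical IQR outlier removal, ecosystem-coverage filter.
#'
#' @param table A `rate_table` from [read_rate_table()].
#' @param config A [preprocess_config()].
#' @return A list with class `preprocess_result`: `matrix` (the filtered
#'   [rate_matrix()]) and `log`, a data.frame counting values and chemicals
#'   surviving each stage.
#' @export
preprocess_rates <- function(table, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  meta <- attr(table, "chemical_meta") %||% .empty_chemical_meta()
  tab <- as.data.frame(table)
  tab <- tab[tab$valid, , drop = FALSE]
  stages <- list()
  note <- function(stage, t, m = NULL) {
    n_val <- if (is.null(m)) nrow(t) else sum(!is.na(m))
    n_chem <- if (is.null(m)) length(unique(t$chemical_id)) else nrow(m)
    stages[[length(stages) + 1]] <<- data.frame(
      stage = stage, n_values = n_val, n_chemicals = n_chem,
      stringsAsFactors = FALSE)
  }
  note("valid input", tab)

  if (config$apply_dissolved_correction) {
    has_f <- !is.na(tab$f_dissolved)
    tab$k[has_f] <- dissolved_correct(tab$k[has_f], tab$f_dissolved[has_f])
  }
  if (config$apply_ph_correction) {
    has_ph <- which(!is.na(tab$pH))
    for (i in has_ph) {
      sites_i <- pka_sites(meta, tab$chemical_id[i])
      if (nrow(sites_i) > 0) {
        tab$k[i] <- ph_correct(tab$k[i], tab$pH[i], sites_i,
                               config$reference_pH)
      }
    }
  }

  m <- pivot_log_matrix(tab)
  note("corrected matrix", NULL, m)

  for (i in seq_len(nrow(m))) {
    present <- which(!is.na(m[i, ]))
    vals <- if (config$outlier_on_log) m[i, present] else 10^m[i, present]
    out <- iqr_outlier_mask(vals, config$iqr_multiplier,
                            config$min_values_for_outlier_test)
    m[i, present[out]] <- NA_real_
  }
  note("after outlier removal", NULL, m)

  m <- coverage_filter(m, config$coverage_fraction)
  note("after coverage filter", NULL, m)

  structure(list(matrix = m, log = do.call(rbind, stages)),
            class = "preprocess_result")
}

#' @export
print.preprocess_result <- function(x, ...) {
  cat("preprocessing result\n")
  print(x$log, row.names = FALSE)
  invisible(x)
}
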