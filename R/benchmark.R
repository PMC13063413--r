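#' Spatiotemporal standard deviation of one chemical's log10 k
#'
#' The sample standard deviation (N - 1 denominator) of a chemical's log10
#' rate constants over its non-missing site-experiments. This is the
#' quantity benchmarking tries to reduce: on the log10 scale a stddev of 0.4
#' corresponds to a 10^0.4 = 2.5-fold spread of rate constants.
#'
#' @param row Named numeric vector, site -> log10 k, `NA` = missing.
#' @param min_n Minimum number of non-missing values required (default 3; the
#'   N - 1 denominator needs at least 2, and 3 keeps degenerate two-point
#'   stddevs out of the medians).
#' @return The standard deviation, log10 units.
#' @export
chemical_stddev <- function(row, min_n = 3L) {
  x <- row[!is.na(row)]
  if (length(x) < min_n) {
    stop_rembench(
      sprintf("need at least %d non-missing values, got %d", min_n, length(x)),
      "rembench_insufficient_data_error")
  }
  stats::sd(x)
}

# core pair computation shared by benchmark_residuals() and rem();
# xi, xb are full site-aligned rows (NA = missing)
.rem_pair <- function(xi, xb, min_n = 3L) {
  vi <- !is.na(xi)
  n <- sum(vi)
  if (n < min_n) {
    stop_rembench(
      sprintf("chemical has %d valid sites; need at least %d", n, min_n),
      "rembench_insufficient_data_error")
  }
  shared <- vi & !is.na(xb)
  if (!any(shared)) {
    stop_rembench("no site where both chemical and benchmark are valid",
                  "rembench_insufficient_overlap_error")
  }
  gap <- vi & is.na(xb)
  d <- xi[shared] - xb[shared]
  res_shared <- d - mean(d)
  # gap rule: where the benchmark is invalid, the chemical's own deviation
  # from its mean over all its valid sites stands in for the benchmarked one
  res_gap <- xi[gap] - mean(xi[vi])
  residuals <- c(res_shared, res_gap)
  names(residuals) <- c(names(xi)[shared], names(xi)[gap])
  stddev_after <- sqrt(sum(residuals^2) / (n - 1))
  list(residuals = residuals,
       n_sites = n,
       n_gap_filled = sum(gap),
       stddev_before = stats::sd(xi[vi]),
       stddev_after = stddev_after)
}

.get_row <- function(matrix, chemical) {
  if (!chemical %in% rownames(matrix)) {
    stop_rembench(sprintf("chemical '%s' not in matrix", chemical),
                  "rembench_usage_error")
  }
  matrix[chemical, ]
}

#' Benchmarked residuals of one chemical against one benchmark
#'
#' At every site where both chemical and benchmark have valid rate
#' constants, the benchmarked log rate is `log10 k_chem - log10 k_bm`; its
#' residual is the deviation from the mean of those differences (the mean
#' plays the role of the reference-site ratio, which is all a stddev-based
#' efficacy measure needs). At sites where the chemical is valid but the
#' benchmark is not, the chemical's own residual, `log10 k - mean(log10 k)`
#' over all its valid sites, fills the missing benchmarked residual.
#'
#' @param matrix A [rate_matrix()].
#' @param chemical,benchmark Chemical tokens (must differ).
#' @param min_n Minimum valid sites for the chemical.
#' @return A list with class `benchmarked_residuals`: `chemical_id`,
#'   `benchmark_id`, `residuals` (named by site), `n_sites`, `n_gap_filled`.
#' @export
benchmark_residuals <- function(matrix, chemical, benchmark, min_n = 3L) {
  if (identical(chemical, benchmark)) {
    stop_rembench("a chemical cannot be benchmarked against itself",
                  "rembench_usage_error")
  }
  pr <- .rem_pair(.get_row(matrix, chemical), .get_row(matrix, benchmark),
                  min_n)
  structure(list(chemical_id = chemical, benchmark_id = benchmark,
                 residuals = pr$residuals, n_sites = pr$n_sites,
                 n_gap_filled = pr$n_gap_filled),
            class = "benchmarked_residuals")
}

#' The REM variance-reduction statistic for one chemical/benchmark pair
#'
#' REM is the reduction in spatiotemporal variability achieved by
#' benchmarking: the stddev of the chemical's log10 k across its valid
#' site-experiments, minus the stddev of the benchmarked residual set (gap
#' rule included, N - 1 denominator with N = the chemical's valid-site
#' count). Positive REM means benchmarking helped.
#'
#' @inheritParams benchmark_residuals
#' @return A list: `stddev_before`, `stddev_after`, `rem` (all log10 units),
#'   `n_sites`, `n_gap_filled`.
#' @export
#' @examples
#' m <- rate_matrix(matrix(c(0, 1, 2, 0.7, 1.7, 2.7), 2, 3, byrow = TRUE,
#'                  dimnames = list(c("A", "B"), c("s1", "s2", "s3"))))
#' rem(m, "B", "A") # perfect benchmark: rem equals stddev_before
rem <- function(matrix, chemical, benchmark, min_n = 3L) {
  if (identical(chemical, benchmark)) {
    stop_rembench("a chemical cannot be benchmarked against itself",
                  "rembench_usage_error")
  }
  pr <- .rem_pair(.get_row(matrix, chemical), .get_row(matrix, benchmark),
                  min_n)
  list(stddev_before = pr$stddev_before,
       stddev_after = pr$stddev_after,
       rem = pr$stddev_before - pr$stddev_after,
       n_sites = pr$n_sites,
       n_gap_filled = pr$n_gap_filled)
}

#' Median REM of a benchmark over a candidate set
#'
#' Evaluates one chemical as benchmark for every candidate and returns the
#' median REM. Candidates with insufficient data (fewer than `min_n` valid
#' sites) or no site overlap with the benchmark are skipped and counted in
#' the `n_skipped` attribute.
#'
#' @param matrix A [rate_matrix()].
#' @param benchmark Benchmark chemical token.
#' @param candidates Character vector of candidate chemicals (the benchmark
#'   itself is excluded automatically).
#' @param min_n Minimum valid sites per candidate.
#' @return Median REM (numeric scalar) with attributes `n_evaluated` and
#'   `n_skipped`.
#' @export
median_rem <- function(matrix, benchmark,
                       candidates = setdiff(rownames(matrix), benchmark),
                       min_n = 3L) {
  candidates <- setdiff(candidates, benchmark)
  rems <- rep(NA_real_, length(candidates))
  for (i in seq_along(candidates)) {
    r <- tryCatch(rem(matrix, candidates[i], benchmark, min_n),
                  rembench_insufficient_data_error = function(e) NULL,
                  rembench_insufficient_overlap_error = function(e) NULL)
    if (!is.null(r)) rems[i] <- r$rem
  }
  ok <- !is.na(rems)
  if (!any(ok)) {
    stop_rembench(
      sprintf("no candidate could be benchmarked against '%s'", benchmark),
      "rembench_insufficient_data_error")
  }
  structure(stats::median(rems[ok]),
            n_evaluated = sum(ok), n_skipped = sum(!ok))
}

#' Select the best benchmark chemical from a pool
#'
#' Every pool member is tested as benchmark against the remaining members;
#' the one with the largest median REM wins (its variability pattern and
#' magnitude best match the rest of the pool). Ties are broken by the
#' lexicographically smallest chemical_id so selection is deterministic.
#'
#' @param matrix A [rate_matrix()].
#' @param pool Character vector of at least two chemicals.
#' @param min_n Minimum valid sites per chemical.
#' @return A list: `benchmark_id` and `rem_table`, a data.frame of each
#'   candidate benchmark's median REM and counts.
#' @export
select_benchmark <- function(matrix, pool = rownames(matrix), min_n = 3L) {
  pool <- sort(unique(pool))
  if (length(pool) < 2) {
    stop_rembench("benchmark selection needs a pool of at least 2 chemicals",
                  "rembench_usage_error")
  }
  tab <- data.frame(benchmark_id = pool, median_rem = NA_real_,
                    n_evaluated = 0L, n_skipped = 0L,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pool)) {
    mr <- tryCatch(median_rem(matrix, pool[i], setdiff(pool, pool[i]), min_n),
                   rembench_insufficient_data_error = function(e) NULL)
    if (!is.null(mr)) {
      tab$median_rem[i] <- as.numeric(mr)
      tab$n_evaluated[i] <- attr(mr, "n_evaluated")
      tab$n_skipped[i] <- attr(mr, "n_skipped")
    }
  }
  if (all(is.na(tab$median_rem))) {
    stop_rembench("no pool member could act as a benchmark",
                  "rembench_insufficient_data_error")
  }
  best <- tab$benchmark_id[order(-tab$median_rem, tab$benchmark_id,
                                 na.last = TRUE)][1]
  list(benchmark_id = best, rem_table = tab)
}

.per_chemical_entry <- function(matrix, chemical, benchmark, group, min_n) {
  r <- tryCatch(rem(matrix, chemical, benchmark, min_n),
                rembench_insufficient_data_error = function(e) NULL,
                rembench_insufficient_overlap_error = function(e) NULL)
  if (is.null(r)) return(NULL)
  data.frame(chemical_id = chemical, group = group, benchmark_id = benchmark,
             n_sites = r$n_sites, n_gap_filled = r$n_gap_filled,
             stddev_before = r$stddev_before, stddev_after = r$stddev_after,
             rem = r$rem, stringsAsFactors = FALSE)
}

.make_benchmark_result <- function(mode, per_chemical, assignments,
                                   rem_tables = NULL, n_skipped = 0L) {
  res <- structure(list(mode = mode,
                        per_chemical = per_chemical,
                        assignments = assignments,
                        rem_tables = rem_tables,
                        n_skipped = n_skipped,
                        summary = NULL),
                   class = "benchmark_result")
  res$summary <- summarize_benchmark(res)
  res
}

#' Universal benchmarking (UBM)
#'
#' Selects one benchmark for the whole data set ([select_benchmark()] over
#' all chemicals) and reports the REM of every other chemical against it.
#' The benchmark chemical has no entry of its own and is excluded from all
#' summary statistics.
#'
#' @param matrix A [rate_matrix()] with at least 2 chemicals.
#' @param min_n Minimum valid sites per chemical.
#' @return A `benchmark_result`: `mode`, `per_chemical` (data.frame),
#'   `assignments` (chemical -> benchmark), `rem_tables` (per-candidate
#'   selection table), `summary` (see [summarize_benchmark()]).
#' @export
run_ubm <- function(matrix, min_n = 3L) {
  sel <- select_benchmark(matrix, rownames(matrix), min_n)
  bm <- sel$benchmark_id
  others <- setdiff(sort(rownames(matrix)), bm)
  entries <- lapply(others, .per_chemical_entry, matrix = matrix,
                    benchmark = bm, group = 1L, min_n = min_n)
  skipped <- sum(vapply(entries, is.null, logical(1)))
  per_chemical <- do.call(rbind, entries) %||% .empty_per_chemical()
  assignments <- stats::setNames(rep(bm, length(others)), others)
  .make_benchmark_result("UBM", per_chemical, assignments,
                         list(`1` = sel$rem_table), skipped)
}

#' Group-specific benchmarking (GBM)
#'
#' Runs [select_benchmark()] independently within each chemical group and
#' benchmarks every non-benchmark group member against its group's
#' benchmark. Summary medians pool all groups, benchmarks excluded.
#'
#' @param matrix A [rate_matrix()].
#' @param grouping A `group_assignment` (named integer vector,
#'   chemical -> group label) covering every chemical in the matrix; every
#'   group must contribute at least 2 matrix chemicals.
#' @param min_n Minimum valid sites per chemical.
#' @return A `benchmark_result`, as [run_ubm()].
#' @export
run_gbm <- function(matrix, grouping, min_n = 3L) {
  chems <- rownames(matrix)
  ungrouped <- setdiff(chems, names(grouping))
  if (length(ungrouped) > 0) {
    stop_rembench(sprintf("no group assigned for chemical(s): %s",
                          paste(ungrouped, collapse = ", ")),
                  "rembench_config_error")
  }
  grp <- grouping[chems]
  sizes <- table(grp)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    stop_rembench(
      sprintf("group(s) with fewer than 2 chemicals in the matrix: %s",
              paste(small, collapse = ", ")),
      "rembench_config_error")
  }
  entries <- list(); assignments <- character(0); rem_tables <- list()
  skipped <- 0L
  for (g in sort(unique(as.integer(grp)))) {
    members <- sort(chems[grp == g])
    sel <- select_benchmark(matrix, members, min_n)
    bm <- sel$benchmark_id
    rem_tables[[as.character(g)]] <- sel$rem_table
    for (chem in setdiff(members, bm)) {
      e <- .per_chemical_entry(matrix, chem, bm, g, min_n)
      if (is.null(e)) skipped <- skipped + 1L else entries[[length(entries) + 1]] <- e
      assignments[chem] <- bm
    }
  }
  per_chemical <- do.call(rbind, entries) %||% .empty_per_chemical()
  .make_benchmark_result("GBM", per_chemical, assignments, rem_tables, skipped)
}

#' TOC normalization as a benchmarking baseline
#'
#' Treats log10 TOC as a pseudo-benchmark: every chemical's rate constants
#' are divided by the site's total organic carbon and the change in stddev
#' is reported, giving a non-chemical reference against which UBM/GBM
#' efficacy can be judged.
#'
#' @param matrix A [rate_matrix()].
#' @param toc_by_site Named numeric vector site -> TOC, as [toc_normalize()].
#' @param min_n Minimum valid sites per chemical.
#' @return A `benchmark_result` with `mode = "TOC"`.
#' @export
run_toc <- function(matrix, toc_by_site, min_n = 3L) {
  normed <- toc_normalize(matrix, toc_by_site)
  entries <- list(); skipped <- 0L
  for (chem in sort(rownames(matrix))) {
    e <- tryCatch({
      before <- chemical_stddev(matrix[chem, ], min_n)
      after <- chemical_stddev(normed[chem, ], min_n)
      data.frame(chemical_id = chem, group = 1L, benchmark_id = "TOC",
                 n_sites = sum(!is.na(matrix[chem, ])), n_gap_filled = 0L,
                 stddev_before = before, stddev_after = after,
                 rem = before - after, stringsAsFactors = FALSE)
    }, rembench_insufficient_data_error = function(e) NULL)
    if (is.null(e)) skipped <- skipped + 1L else entries[[length(entries) + 1]] <- e
  }
  per_chemical <- do.call(rbind, entries) %||% .empty_per_chemical()
  assignments <- stats::setNames(rep("TOC", nrow(per_chemical)),
                                 per_chemical$chemical_id)
  .make_benchmark_result("TOC", per_chemical, assignments, NULL, skipped)
}

.empty_per_chemical <- function() {
  data.frame(chemical_id = character(), group = integer(),
             benchmark_id = character(), n_sites = integer(),
             n_gap_filled = integer(), stddev_before = numeric(),
             stddev_after = numeric(), rem = numeric(),
             stringsAsFactors = FALSE)
}

#' Express a log10 quantity as a multiplicative fold factor
#'
#' Stddevs and REMs live on the log10 scale; `10^x` converts them to the
#' fold difference practitioners quote (a stddev of 0.4 in log10 k is a
#' 2.5-fold spread of k).
#'
#' @param x Value in log10 units.
#' @return `10^x`.
#' @export
fold_factor <- function(x) 10^x

#' Summary statistics of a benchmarking result
#'
#' @param result A `benchmark_result`.
#' @return A list: `median_rem`, `fraction_rem_positive` (share of
#'   non-benchmark chemicals whose stddev was reduced), fold-factor
#'   versions, and a per-group data.frame with each group's benchmark and
#'   median REM. Medians exclude benchmark chemicals (they have no entries).
#' @export
summarize_benchmark <- function(result) {
  pc <- result$per_chemical
  if (nrow(pc) == 0) {
    return(list(median_rem = NA_real_, median_fold_factor = NA_real_,
                fraction_rem_positive = NA_real_,
                per_group = data.frame(group = integer(),
                                       benchmark_id = character(),
                                       n_chemicals = integer(),
                                       median_rem = numeric(),
                                       stringsAsFactors = FALSE),
                n_skipped = result$n_skipped))
  }
  per_group <- do.call(rbind, lapply(sort(unique(pc$group)), function(g) {
    sub <- pc[pc$group == g, , drop = FALSE]
    data.frame(group = g, benchmark_id = sub$benchmark_id[1],
               n_chemicals = nrow(sub), median_rem = stats::median(sub$rem),
               stringsAsFactors = FALSE)
  }))
  list(median_rem = stats::median(pc$rem),
       median_fold_factor = fold_factor(stats::median(pc$rem)),
       fraction_rem_positive = mean(pc$rem > 0),
       per_group = per_group,
       n_skipped = result$n_skipped)
}

#' @export
print.benchmark_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s benchmarking: %d chemicals benchmarked (%d skipped)\n",
              x$mode, nrow(x$per_chemical), x$n_skipped))
  if (nrow(x$per_chemical) > 0) {
    cat(sprintf("  median REM %.4f (fold factor %.2f); stddev reduced for %.0f%% of chemicals\n",
                s$median_rem, s$median_fold_factor,
                100 * s$fraction_rem_positive))
    if (nrow(s$per_group) > 1) {
      cat(sprintf("  %d groups; per-group median REM %.3f to %.3f\n",
                  nrow(s$per_group), min(s$per_group$median_rem),
                  max(s$per_group$median_rem)))
    }
  }
  invisible(x)
}
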