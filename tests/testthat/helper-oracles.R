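# Independent oracles, written as direct transcriptions of the definitions
# and kept free of any code shared with the implementation.

# Brute-force benchmarking: stddev of log k before, stddev of the
# benchmarked residual set after (gap rule included), REM = difference.
# xi, xb: full site-aligned numeric vectors with NA for missing.
brute_rem <- function(xi, xb, min_n = 3L) {
  valid_i <- which(!is.na(xi))
  n <- length(valid_i)
  if (n < min_n) return(NULL)
  shared <- valid_i[!is.na(xb[valid_i])]
  if (length(shared) == 0) return(NULL)
  gap <- setdiff(valid_i, shared)

  mean_before <- sum(xi[valid_i]) / n
  stddev_before <- sqrt(sum((xi[valid_i] - mean_before)^2) / (n - 1))

  logk_prime <- xi[shared] - xb[shared]
  res <- numeric(0)
  for (j in shared) res <- c(res, (xi[j] - xb[j]) - mean(logk_prime))
  for (j in gap) res <- c(res, xi[j] - mean_before)
  stddev_after <- sqrt(sum(res^2) / (n - 1))
  list(stddev_before = stddev_before, stddev_after = stddev_after,
       rem = stddev_before - stddev_after, n_gap_filled = length(gap))
}

# Brute-force Ward agglomeration with exhaustive recomputation of the
# error sum of squares at every step. Heights on the distance scale
# (sqrt(2 * increase in ESS)). Returns, per merge, the two member sets
# (sorted index vectors) and the height.
brute_ward <- function(x) {
  ess <- function(idx) {
    c0 <- colMeans(x[idx, , drop = FALSE])
    sum(sweep(x[idx, , drop = FALSE], 2, c0)^2)
  }
  clusters <- lapply(seq_len(nrow(x)), identity)
  steps <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (a in seq_len(length(clusters) - 1)) {
      for (b in (a + 1):length(clusters)) {
        d <- ess(c(clusters[[a]], clusters[[b]])) -
          ess(clusters[[a]]) - ess(clusters[[b]])
        if (is.null(best) || d < best$d - 1e-12) best <- list(a = a, b = b, d = d)
      }
    }
    steps[[length(steps) + 1]] <- list(
      members = list(sort(clusters[[best$a]]), sort(clusters[[best$b]])),
      height = sqrt(2 * max(best$d, 0)))
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  steps
}

# Merge steps of an hclust tree in the same shape as brute_ward()
hclust_steps <- function(tree) {
  members <- list()
  steps <- list()
  for (i in seq_len(nrow(tree$merge))) {
    get <- function(v) if (v < 0) -v else members[[v]]
    a <- sort(get(tree$merge[i, 1])); b <- sort(get(tree$merge[i, 2]))
    members[[i]] <- sort(c(a, b))
    steps[[i]] <- list(members = list(a, b), height = tree$height[i])
  }
  steps
}

# Do two merge-step lists describe the same agglomeration?
same_merge_sequence <- function(s1, s2, tol = 1e-8) {
  if (length(s1) != length(s2)) return(FALSE)
  for (i in seq_along(s1)) {
    p1 <- s1[[i]]$members; p2 <- s2[[i]]$members
    pair_equal <- (identical(p1[[1]], p2[[1]]) && identical(p1[[2]], p2[[2]])) ||
      (identical(p1[[1]], p2[[2]]) && identical(p1[[2]], p2[[1]]))
    if (!pair_equal) return(FALSE)
    if (abs(s1[[i]]$height - s2[[i]]$height) > tol) return(FALSE)
  }
  TRUE
}

# Random gappy rate matrix for property tests
random_rate_matrix <- function(n_chem, n_sites, p_missing = 0.2) {
  m <- matrix(stats::rnorm(n_chem * n_sites), n_chem, n_sites,
              dimnames = list(sprintf("C%02d", seq_len(n_chem)),
                              sprintf("S%02d", seq_len(n_sites))))
  m[matrix(stats::runif(length(m)) < p_missing, n_chem)] <- NA_real_
  rate_matrix(m)
}

# A matrix whose rows are the given rows (named list) over shared sites
matrix_from_rows <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- sprintf("s%d", seq_len(ncol(m)))
  rate_matrix(m)
}
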