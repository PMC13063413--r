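#' Construct a group assignment
#'
#' A named integer vector chemical -> group label, relabelled to contiguous
#' integers starting at 1 (in order of first appearance).
#'
#' @param labels Named integer (or coercible) vector of group labels.
#' @param method How the grouping was obtained: `"pearson"`, `"maccs"`,
#'   `"btrules"`, `"btrules_prob"`, `"file"`, or `"true"` (simulated truth).
#' @param k_requested Optionally, the cluster count that was asked for
#'   (before any minimum-size repair).
#' @return A `group_assignment`.
#' @export
group_assignment <- function(labels, method = "file", k_requested = NULL) {
  if (is.null(names(labels)) || anyDuplicated(names(labels))) {
    stop_rembench("labels must be uniquely named by chemical_id",
                  "rembench_validation_error")
  }
  lab <- as.integer(factor(as.integer(labels),
                           levels = unique(as.integer(labels))))
  names(lab) <- names(labels)
  structure(lab, method = method,
            k_requested = k_requested %||% length(unique(lab)),
            k_effective = length(unique(lab)),
            class = "group_assignment")
}

#' @export
print.group_assignment <- function(x, ...) {
  cat(sprintf("group_assignment (%s): %d chemicals in %d groups\n",
              attr(x, "method"), length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Pairwise Pearson correlations between chemicals' log k profiles
#'
#' Computes r for every pair of chemicals over their pairwise-complete
#' site-experiments (cells where both are non-missing). Pairs with fewer
#' than `min_overlap` shared sites, or with zero variance in either profile
#' over the shared sites, get a missing r; the shared-site counts are always
#' recorded.
#'
#' @param matrix A [rate_matrix()] with at least 2 chemicals.
#' @param min_overlap Minimum number of shared sites for r to be computed.
#' @return A list with class `correlation_matrix`: `r` (symmetric, diagonal
#'   1, `NA` where undefined) and `n_overlap` (integer matrix).
#' @export
pairwise_pearson <- function(matrix, min_overlap = 5L) {
  n <- nrow(matrix)
  if (n < 2) {
    stop_rembench("need at least 2 chemicals", "rembench_usage_error")
  }
  chems <- rownames(matrix)
  r <- matrix(NA_real_, n, n, dimnames = list(chems, chems))
  n_overlap <- matrix(0L, n, n, dimnames = list(chems, chems))
  present <- !is.na(matrix)
  diag(r) <- 1
  diag(n_overlap) <- rowSums(present)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- present[i, ] & present[j, ]
      m <- sum(shared)
      n_overlap[i, j] <- n_overlap[j, i] <- m
      if (m >= min_overlap) {
        xi <- matrix[i, shared]; xj <- matrix[j, shared]
        if (stats::sd(xi) > 0 && stats::sd(xj) > 0) {
          r[i, j] <- r[j, i] <- stats::cor(xi, xj)
        }
      }
    }
  }
  structure(list(r = r, n_overlap = n_overlap, min_overlap = min_overlap),
            class = "correlation_matrix")
}

#' Correlation-profile feature vectors
#'
#' Each chemical's clustering feature vector is its row of the pairwise
#' correlation matrix: how its log k profile co-varies with every other
#' chemical's. Missing correlations are imputed with 0 (no information);
#' the diagonal stays 1, which adds the same constant coordinate to every
#' vector and leaves between-chemical Euclidean distances driven by the
#' off-diagonal correlations.
#'
#' @param corr A `correlation_matrix` from [pairwise_pearson()].
#' @return A chemicals x chemicals numeric feature matrix.
#' @export
correlation_features <- function(corr) {
  f <- corr$r
  f[is.na(f)] <- 0
  diag(f) <- 1
  f
}

#' Agglomerative Ward clustering of feature vectors
#'
#' Hierarchical clustering under Euclidean distance with Ward's
#' minimum-variance criterion in the "Ward.D2" convention (squared distances
#' in the update; merge heights on the distance scale, so two singletons a
#' distance d apart merge at height d). Deterministic given the input.
#'
#' @param features Numeric items x dimensions matrix with item row names;
#'   binary descriptor vectors are treated as 0/1 reals, making Euclidean
#'   distance the square root of the Hamming distance.
#' @return An [stats::hclust] tree with the feature matrix attached as
#'   attribute `features` (used by [cut_tree_min_size()]).
#' @export
ward_tree <- function(features) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (nrow(features) < 2) {
    stop_rembench("need at least 2 items to cluster", "rembench_usage_error")
  }
  if (any(!is.finite(features))) {
    stop_rembench("features must be finite", "rembench_domain_error")
  }
  tree <- stats::hclust(stats::dist(features, method = "euclidean"),
                        method = "ward.D2")
  attr(tree, "features") <- features
  tree
}

# Ward.D2 linkage distance between two clusters given member feature rows:
# sqrt(2 * |A||B| / (|A|+|B|) * ||centroid_A - centroid_B||^2)
.ward_linkage <- function(features, a, b) {
  ca <- colMeans(features[a, , drop = FALSE])
  cb <- colMeans(features[b, , drop = FALSE])
  na <- length(a); nb <- length(b)
  sqrt(2 * na * nb / (na + nb) * sum((ca - cb)^2))
}

#' Cut a Ward tree with a minimum cluster size
#'
#' Cuts the tree into `k_groups` clusters, then repairs undersized clusters:
#' while any cluster has fewer than `min_size` members, the smallest one is
#' merged into the cluster at the smallest Ward linkage distance from it,
#' reducing the effective group count. Group-specific benchmarking needs at
#' least two chemicals per group (one benchmark plus one test chemical),
#' hence the default `min_size = 2`.
#'
#' @param tree A tree from [ward_tree()] (must carry its `features`).
#' @param k_groups Requested number of clusters, between 1 and the leaf
#'   count.
#' @param min_size Minimum cluster size (1 disables the repair).
#' @param method Method tag recorded on the result.
#' @return A [group_assignment()]; attributes `k_requested` and
#'   `k_effective` report the requested and post-repair group counts.
#' @export
cut_tree_min_size <- function(tree, k_groups, min_size = 2L,
                              method = "pearson") {
  n <- length(tree$labels)
  if (k_groups < 1 || k_groups > n) {
    stop_rembench(sprintf("k_groups must be in [1, %d]", n),
                  "rembench_usage_error")
  }
  labels <- stats::cutree(tree, k = k_groups)
  features <- attr(tree, "features")
  if (min_size > 1 && is.null(features)) {
    stop_rembench("tree lacks its feature matrix; build it with ward_tree()",
                  "rembench_usage_error")
  }
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0 || length(sizes) == 1) break
    # absorb the smallest offender into its Ward-nearest cluster
    victim <- small[order(sizes[small], small)][1]
    others <- setdiff(names(sizes), victim)
    idx_v <- which(labels == as.integer(victim))
    d <- vapply(others, function(o) {
      .ward_linkage(features, idx_v, which(labels == as.integer(o)))
    }, numeric(1))
    target <- others[order(d, as.integer(others))][1]
    labels[idx_v] <- as.integer(target)
  }
  group_assignment(labels, method = method, k_requested = as.integer(k_groups))
}

#' Group chemicals by structural / biotransformation descriptors
#'
#' Data-independent grouping: Ward clustering ([ward_tree()]) of the
#' chemicals' descriptor vectors (MACCS fingerprints, biotransformation-rule
#' triggers, or rule probabilities), cut plainly at `k_groups` with no
#' minimum-size repair.
#'
#' @param desc A `descriptor_matrix` (see [read_descriptor_matrix()]).
#' @param k_groups Number of clusters.
#' @param chemicals Chemicals to group (default: all rows of `desc`); every
#'   one must be present in `desc`.
#' @return A [group_assignment()] tagged with the descriptor kind.
#' @export
descriptor_grouping <- function(desc, k_groups, chemicals = rownames(desc)) {
  absent <- setdiff(chemicals, rownames(desc))
  if (length(absent) > 0) {
    stop_rembench(sprintf("chemical(s) missing from descriptor matrix: %s",
                          paste(absent, collapse = ", ")),
                  "rembench_config_error")
  }
  features <- unclass(desc)[chemicals, , drop = FALSE]
  tree <- ward_tree(features)
  labels <- stats::cutree(tree, k = k_groups)
  group_assignment(labels, method = attr(desc, "kind") %||% "custom",
                   k_requested = as.integer(k_groups))
}

#' Data-dependent ("optimized") grouping from the rate matrix itself
#'
#' The grouping behind optimized group-specific benchmarking: chemicals are
#' clustered on their profiles of pairwise Pearson correlations of log10 k
#' ([pairwise_pearson()] then [correlation_features()]), by Ward clustering
#' with the minimum-cluster-size repair.
#'
#' @param matrix A [rate_matrix()].
#' @param k_groups Requested number of groups.
#' @param min_overlap Minimum shared sites for a correlation (default 5).
#' @param min_size Minimum chemicals per group (default 2).
#' @return A [group_assignment()] with method `"pearson"`.
#' @export
pearson_grouping <- function(matrix, k_groups, min_overlap = 5L,
                             min_size = 2L) {
  corr <- pairwise_pearson(matrix, min_overlap)
  tree <- ward_tree(correlation_features(corr))
  cut_tree_min_size(tree, k_groups, min_size, method = "pearson")
}
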