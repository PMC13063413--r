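#' Configuration for the synthetic rate-constant generator
#'
#' The generator emulates the variance structure the benchmarking analysis
#' assumes: each chemical has a mean log10 rate constant, chemicals in the
#' same group share a site effect (the "biodegradation capacity" of each
#' site-experiment for that group of chemicals), and independent Gaussian
#' measurement noise sits on top:
#'
#' `log10 k[i, j] = mu_i + lambda_i * delta[g(i), j] + eps[i, j]`
#'
#' with `delta ~ N(0, sigma_group^2)` drawn per (group, site) and
#' `eps ~ N(0, sigma_noise^2)` i.i.d. Cells are removed completely at
#' random with probability `p_missing` (or censored below a log10 k
#' threshold via `censor_below`, emulating rate constants not significantly
#' different from zero), and optionally shifted by `+/- outlier_shift` with
#' probability `outlier_rate`.
#'
#' Defaults mirror the study conditions the analysis was designed for:
#' 8 groups x 8 chemicals over 38 site-experiments, group-effect stddev 0.3
#' and noise stddev 0.1 (log10 units; spatiotemporal variability a few-fold
#' larger than measurement uncertainty), 20% missing values, and chemical
#' mean log10 k drawn uniformly from \[-3, 1\] (rate constants of roughly
#' 0.001 to 10 per day).
#'
#' @param n_groups Number of chemical groups.
#' @param chemicals_per_group Chemicals per group (scalar, or one count per
#'   group).
#' @param n_sites Number of site-experiments (>= 3).
#' @param mu_range Interval for per-chemical mean log10 k.
#' @param sigma_group Stddev of the group-shared site effects, log10 units.
#' @param sigma_noise Stddev of the independent noise, log10 units.
#' @param loading_range Interval for the per-chemical loading on the group
#'   effect; degenerate at 1 by default.
#' @param p_missing Probability a cell is missing, in [0, 1).
#' @param outlier_rate Probability a cell is shifted by an outlier.
#' @param outlier_shift Outlier magnitude, log10 units (sign is random).
#' @param censor_below Optional log10 k threshold below which cells are
#'   removed (value-dependent censoring), `NULL` to disable.
#' @return A list with class `sim_config`.
#' @export
sim_config <- function(n_groups = 8L, chemicals_per_group = 8L,
                       n_sites = 38L, mu_range = c(-3, 1),
                       sigma_group = 0.3, sigma_noise = 0.1,
                       loading_range = c(1, 1), p_missing = 0.2,
                       outlier_rate = 0, outlier_shift = 3,
                       censor_below = NULL) {
  if (length(chemicals_per_group) == 1) {
    chemicals_per_group <- rep(as.integer(chemicals_per_group), n_groups)
  }
  ok <- n_groups >= 1 && length(chemicals_per_group) == n_groups &&
    all(chemicals_per_group >= 1) && n_sites >= 3 &&
    length(mu_range) == 2 && mu_range[1] <= mu_range[2] &&
    sigma_group >= 0 && sigma_noise >= 0 &&
    length(loading_range) == 2 && loading_range[1] <= loading_range[2] &&
    p_missing >= 0 && p_missing < 1 && outlier_rate >= 0 &&
    p_missing + outlier_rate < 1
  if (!ok) {
    stop_rembench("invalid simulation configuration",
                  "rembench_validation_error")
  }
  structure(list(n_groups = as.integer(n_groups),
                 chemicals_per_group = as.integer(chemicals_per_group),
                 n_sites = as.integer(n_sites), mu_range = mu_range,
                 sigma_group = sigma_group, sigma_noise = sigma_noise,
                 loading_range = loading_range, p_missing = p_missing,
                 outlier_rate = outlier_rate, outlier_shift = outlier_shift,
                 censor_below = censor_below),
            class = "sim_config")
}

# per-component sub-seeds so toggling one stochastic component does not
# reshuffle the others
.component_seeds <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  stats::setNames(sample.int(2^31 - 2, 6),
                  c("mu", "effects", "loadings", "noise", "missing",
                    "outliers"))
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a group-structured rate-constant data set
#'
#' Draws a data set from the model described in [sim_config()], in a fixed
#' order (group effects, then chemical parameters, then noise, missingness
#' and outliers) with one deterministic sub-seed per stochastic component.
#'
#' @param config A [sim_config()].
#' @param seed Master integer seed; the same config and seed always give an
#'   identical data set.
#' @return A list with class `simulated_dataset`: `matrix` (a
#'   [rate_matrix()]), `true_groups` (a [group_assignment()]), `true_params`
#'   (`mu`, `loadings`, `delta` the group x site effects), and `config`.
#' @export
simulate_rates <- function(config = sim_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- .component_seeds(seed)
  n_chem <- sum(config$chemicals_per_group)
  chems <- sprintf("C%03d", seq_len(n_chem))
  sites <- sprintf("S%02d", seq_len(config$n_sites))
  group_of <- rep(seq_len(config$n_groups), config$chemicals_per_group)

  delta <- .with_seed(seeds[["effects"]], matrix(
    stats::rnorm(config$n_groups * config$n_sites, 0, config$sigma_group),
    config$n_groups, config$n_sites))
  mu <- .with_seed(seeds[["mu"]],
                   stats::runif(n_chem, config$mu_range[1], config$mu_range[2]))
  loadings <- .with_seed(seeds[["loadings"]],
                         stats::runif(n_chem, config$loading_range[1],
                                      config$loading_range[2]))
  eps <- .with_seed(seeds[["noise"]], matrix(
    stats::rnorm(n_chem * config$n_sites, 0, config$sigma_noise),
    n_chem, config$n_sites))

  logk <- mu + loadings * delta[group_of, , drop = FALSE] + eps
  dimnames(logk) <- list(chems, sites)

  if (config$outlier_rate > 0) {
    logk <- .with_seed(seeds[["outliers"]], {
      hit <- matrix(stats::runif(length(logk)) < config$outlier_rate,
                    nrow(logk))
      sign <- matrix(sample(c(-1, 1), length(logk), replace = TRUE),
                     nrow(logk))
      logk + hit * sign * config$outlier_shift
    })
  }
  if (config$p_missing > 0) {
    logk <- .with_seed(seeds[["missing"]], {
      logk[matrix(stats::runif(length(logk)) < config$p_missing,
                  nrow(logk))] <- NA_real_
      logk
    })
  }
  if (!is.null(config$censor_below)) {
    logk[!is.na(logk) & logk < config$censor_below] <- NA_real_
  }

  structure(list(matrix = rate_matrix(logk),
                 true_groups = group_assignment(
                   stats::setNames(group_of, chems), method = "true"),
                 true_params = list(mu = stats::setNames(mu, chems),
                                    loadings = stats::setNames(loadings, chems),
                                    delta = delta),
                 config = config),
            class = "simulated_dataset")
}

#' Large-N expected REM for a within-group benchmark
#'
#' Under the generator's model with unit loadings and no gaps, a chemical's
#' stddev of log10 k tends to `sqrt(sigma_group^2 + sigma_noise^2)` and the
#' benchmarked residuals (difference of two independent noise terms) have
#' stddev `sqrt(2) * sigma_noise`, so
#'
#' `E(REM) ~ sqrt(sigma_group^2 + sigma_noise^2) - sqrt(2) * sigma_noise`.
#'
#' Negative when the group effect is weak: benchmarking against an
#' uncorrelated chemical adds noise instead of removing signal.
#'
#' @param config A [sim_config()] with degenerate loadings at 1.
#' @return Expected within-group REM, log10 units.
#' @export
expected_rem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(config$loading_range[1], config$loading_range[2]) ||
      config$loading_range[1] != 1) {
    stop_rembench("expected_rem supports unit loadings only",
                  "rembench_not_supported_error")
  }
  sqrt(config$sigma_group^2 + config$sigma_noise^2) -
    sqrt(2) * config$sigma_noise
}

#' Degrade an existing rate matrix
#'
#' Reproducibly injects additional missingness and outliers into a matrix,
#' for stress-testing the outlier and gap-filling rules.
#'
#' @param matrix A [rate_matrix()].
#' @param p_missing Probability each non-missing cell is removed (1 wipes
#'   the targeted rows entirely).
#' @param outlier_rate Probability each surviving cell is shifted.
#' @param outlier_shift Shift magnitude, log10 units (random sign).
#' @param seed Integer seed.
#' @param chemicals Rows to degrade (default: all).
#' @return The degraded [rate_matrix()] with attribute `outlier_cells`, an
#'   index matrix of the injected outliers.
#' @export
degrade <- function(matrix, p_missing = 0, outlier_rate = 0,
                    outlier_shift = 3, seed = 1L,
                    chemicals = rownames(matrix)) {
  if (p_missing < 0 || p_missing > 1 || outlier_rate < 0 ||
      outlier_rate >= 1) {
    stop_rembench("p_missing must lie in [0, 1] and outlier_rate in [0, 1)",
                  "rembench_validation_error")
  }
  absent <- setdiff(chemicals, rownames(matrix))
  if (length(absent) > 0) {
    stop_rembench(sprintf("chemical(s) not in matrix: %s",
                          paste(absent, collapse = ", ")),
                  "rembench_validation_error")
  }
  seeds <- .component_seeds(seed)
  m <- unclass(matrix)
  target <- rownames(m) %in% chemicals
  if (outlier_rate > 0) {
    m <- .with_seed(seeds[["outliers"]], {
      hit <- matrix(stats::runif(length(m)) < outlier_rate, nrow(m)) &
        !is.na(m) & target
      sign <- matrix(sample(c(-1, 1), length(m), replace = TRUE), nrow(m))
      m + ifelse(hit, sign * outlier_shift, 0)
    })
    outlier_cells <- which(!is.na(m) & m != unclass(matrix), arr.ind = TRUE)
  } else {
    outlier_cells <- which(matrix(FALSE, nrow(m), ncol(m)), arr.ind = TRUE)
  }
  if (p_missing > 0) {
    m <- .with_seed(seeds[["missing"]], {
      m[matrix(stats::runif(length(m)) <= p_missing, nrow(m)) & target] <- NA_real_
      m
    })
  }
  out <- rate_matrix(m)
  attr(out, "outlier_cells") <- outlier_cells
  out
}
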