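#' Read a long-format rate-constant table
#'
#' Reads a delimited text file (comma or tab, autodetected from the file
#' extension) of first-order biodegradation rate constants, one row per
#' chemical x site-experiment. A site-experiment is one incubation with water
#' and sediment from one location at one sampling time; seasonal repeats at a
#' location are distinct `site_id`s, so the standard deviation across
#' site-experiments pools spatial and temporal (seasonal) variability.
#'
#' Required columns (after applying `dialect`): `chemical_id`, `site_id`, `k`
#' (first-order rate constant, 1/day). Optional columns: `valid` (logical;
#' whether k was significantly different from zero; missing column means all
#' rows valid), `pH`, `f_dissolved` (fraction of the chemical freely
#' dissolved, in (0, 1]), `toc` (total organic carbon of the system), and
#' `replicate_stddev` (standard deviation of log10 k across test-treatment
#' replicates, log10 units).
#'
#' @param path Path to the delimited rates file.
#' @param chemicals_path Optional path to a companion chemical-metadata file,
#'   see [read_chemical_meta()].
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g. `c(k = "rate_constant")`, so
#'   external tables can be adapted without editing them.
#' @return A `rate_table`: a data.frame with the canonical columns above and a
#'   `chemical_meta` attribute (possibly empty) holding speciation metadata.
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("chemical_id,site_id,k", "DIU,s1,0.2", "DIU,s2,0.4",
#'              "FFA,s1,0.1"), f)
#' read_rate_table(f)
read_rate_table <- function(path, chemicals_path = NULL, dialect = NULL) {
  df <- .read_delim(path)
  df <- .apply_dialect(df, dialect)

  required <- c("chemical_id", "site_id", "k")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_rembench(
      sprintf("rate table '%s' lacks required column(s): %s",
              path, paste(missing_cols, collapse = ", ")),
      "rembench_format_error")
  }

  out <- data.frame(
    chemical_id = as.character(df$chemical_id),
    site_id = as.character(df$site_id),
    k = as.numeric(df$k),
    stringsAsFactors = FALSE
  )
  out$valid <- if ("valid" %in% names(df)) .as_logical(df$valid) else TRUE
  out$valid[is.na(out$valid)] <- TRUE
  for (col in c("pH", "f_dissolved", "toc", "replicate_stddev")) {
    out[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  }

  bad_k <- which(out$valid & (!is.finite(out$k) | out$k <= 0))
  if (length(bad_k) > 0) {
    stop_rembench(
      sprintf("valid rows must have k > 0; offending row(s): %s",
              paste(bad_k, collapse = ", ")),
      "rembench_validation_error", rows = bad_k)
  }
  bad_f <- which(!is.na(out$f_dissolved) &
                   (out$f_dissolved <= 0 | out$f_dissolved > 1))
  if (length(bad_f) > 0) {
    stop_rembench(
      sprintf("f_dissolved must lie in (0, 1]; offending row(s): %s",
              paste(bad_f, collapse = ", ")),
      "rembench_validation_error", rows = bad_f)
  }
  bad_sd <- which(!is.na(out$replicate_stddev) & out$replicate_stddev < 0)
  if (length(bad_sd) > 0) {
    stop_rembench(
      sprintf("replicate_stddev must be >= 0; offending row(s): %s",
              paste(bad_sd, collapse = ", ")),
      "rembench_validation_error", rows = bad_sd)
  }

  meta <- if (!is.null(chemicals_path)) read_chemical_meta(chemicals_path)
          else .empty_chemical_meta()
  attr(out, "chemical_meta") <- meta
  class(out) <- c("rate_table", "data.frame")
  out
}

.apply_dialect <- function(df, dialect) {
  if (is.null(dialect)) return(df)
  stopifnot(is.character(dialect), !is.null(names(dialect)))
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (src %in% names(df)) names(df)[names(df) == src] <- canon
  }
  df
}

.as_logical <- function(x) {
  if (is.logical(x)) return(x)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Read chemical metadata (speciation sites)
#'
#' Long-format delimited file with one row per ionizable site: columns
#' `chemical_id`, optional `name`, `pka` (numeric) and `type` (`"acid"` or
#' `"base"`). A chemical absent from the file, or present with empty
#' `pka`/`type`, is treated as permanently neutral.
#'
#' @param path Path to the delimited metadata file.
#' @return A `chemical_meta` data.frame with columns `chemical_id`, `name`,
#'   `pka`, `type`.
#' @export
read_chemical_meta <- function(path) {
  df <- .read_delim(path)
  if (!"chemical_id" %in% names(df)) {
    stop_rembench(
      sprintf("chemical metadata '%s' lacks required column 'chemical_id'",
              path),
      "rembench_format_error")
  }
  out <- data.frame(
    chemical_id = as.character(df$chemical_id),
    name = if ("name" %in% names(df)) as.character(df$name) else NA_character_,
    pka = if ("pka" %in% names(df)) as.numeric(df$pka) else NA_real_,
    type = if ("type" %in% names(df)) as.character(df$type) else NA_character_,
    stringsAsFactors = FALSE
  )
  has_site <- !is.na(out$pka)
  bad <- has_site & (!is.finite(out$pka) | !(out$type %in% c("acid", "base")))
  if (any(bad)) {
    stop_rembench(
      sprintf("pKa rows must have finite pka and type in {acid, base}; offending chemical(s): %s",
              paste(unique(out$chemical_id[bad]), collapse = ", ")),
      "rembench_validation_error")
  }
  class(out) <- c("chemical_meta", "data.frame")
  out
}

.empty_chemical_meta <- function() {
  out <- data.frame(chemical_id = character(), name = character(),
                    pka = numeric(), type = character(),
                    stringsAsFactors = FALSE)
  class(out) <- c("chemical_meta", "data.frame")
  out
}

#' Extract the speciation-site list for one chemical
#'
#' @param meta A `chemical_meta` data.frame.
#' @param chemical_id Chemical token.
#' @return A data.frame with columns `pka`, `type`; zero rows for a
#'   permanently neutral chemical.
#' @export
pka_sites <- function(meta, chemical_id) {
  if (is.null(meta) || nrow(meta) == 0) {
    return(data.frame(pka = numeric(), type = character()))
  }
  rows <- meta[meta$chemical_id == chemical_id & !is.na(meta$pka), , drop = FALSE]
  data.frame(pka = rows$pka, type = rows$type, stringsAsFactors = FALSE)
}

#' Construct / validate a rate matrix
#'
#' The central container of the analysis: a chemicals x site-experiments
#' matrix of log10 rate constants (log10 1/day) with `NA` marking missing
#' (invalid) measurements. Rows are chemicals, columns site-experiments; both
#' dimnames are mandatory and unique.
#'
#' @param logk Numeric matrix of log10 rate constants with chemical row names
#'   and site column names; `NA` = missing.
#' @return The validated matrix with class `rate_matrix`.
#' @export
rate_matrix <- function(logk) {
  if (!is.matrix(logk) || !is.numeric(logk)) {
    stop_rembench("logk must be a numeric matrix", "rembench_validation_error")
  }
  chem <- rownames(logk); sites <- colnames(logk)
  if (is.null(chem) || is.null(sites)) {
    stop_rembench("rate matrix needs chemical row names and site column names",
                  "rembench_validation_error")
  }
  if (anyDuplicated(chem)) {
    stop_rembench("duplicated chemical_id in rate matrix",
                  "rembench_validation_error")
  }
  if (anyDuplicated(sites)) {
    stop_rembench("duplicated site_id in rate matrix",
                  "rembench_validation_error")
  }
  if (any(!is.na(logk) & !is.finite(logk))) {
    stop_rembench("non-missing cells of a rate matrix must be finite",
                  "rembench_validation_error")
  }
  class(logk) <- c("rate_matrix", class(unclass(logk)))
  logk
}

#' @export
print.rate_matrix <- function(x, ...) {
  cat(sprintf("rate_matrix: %d chemicals x %d site-experiments (%.1f%% missing)\n",
              nrow(x), ncol(x), 100 * mean(is.na(x))))
  invisible(x)
}

#' Pivot a rate table into the log10 rate matrix
#'
#' Builds the chemicals x sites grid of log10 k from the valid records of a
#' rate table. Invalid records (k not significantly different from zero)
#' become missing cells. Chemical and site orders are sorted lexicographically
#' so repeated runs are byte-identical.
#'
#' @param table A `rate_table` from [read_rate_table()] (or any data.frame
#'   with columns `chemical_id`, `site_id`, `k`, optionally `valid`).
#' @return A [rate_matrix()].
#' @export
pivot_log_matrix <- function(table) {
  if (nrow(table) == 0) {
    stop_rembench("rate table is empty", "rembench_validation_error")
  }
  valid <- if ("valid" %in% names(table)) table$valid else TRUE
  tab <- table[valid, , drop = FALSE]
  key <- paste(tab$chemical_id, tab$site_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stop_rembench(
      sprintf("duplicate valid records for (chemical, site) pair(s): %s",
              paste(gsub("\r", ", ", dup), collapse = "; ")),
      "rembench_validation_error")
  }
  chemicals <- sort(unique(table$chemical_id))
  sites <- sort(unique(table$site_id))
  m <- matrix(NA_real_, length(chemicals), length(sites),
              dimnames = list(chemicals, sites))
  m[cbind(match(tab$chemical_id, chemicals), match(tab$site_id, sites))] <-
    log10(tab$k)
  rate_matrix(m)
}

#' Write / read a rate matrix as wide delimited text
#'
#' First column `chemical_id`, remaining columns one per site; empty fields
#' mark missing cells (never a sentinel number). Non-missing values
#' round-trip at full double precision (17 significant digits).
#'
#' @param matrix A [rate_matrix()].
#' @param path Output path (`.csv` comma, `.tsv`/`.txt` tab).
#' @return `write_rate_matrix`: the path, invisibly. `read_rate_matrix`: a
#'   [rate_matrix()].
#' @export
write_rate_matrix <- function(matrix, path) {
  df <- data.frame(chemical_id = rownames(matrix), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(matrix))) {
    df[[colnames(matrix)[j]]] <- sprintf("%.17g", matrix[, j])
    df[[colnames(matrix)[j]]][is.na(matrix[, j])] <- NA
  }
  .write_delim(df, path)
  invisible(path)
}

#' @rdname write_rate_matrix
#' @export
read_rate_matrix <- function(path) {
  df <- .read_delim(path)
  if (!"chemical_id" %in% names(df)) {
    stop_rembench(sprintf("matrix file '%s' lacks column 'chemical_id'", path),
                  "rembench_format_error")
  }
  m <- as.matrix(df[, setdiff(names(df), "chemical_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$chemical_id)
  rate_matrix(m)
}

#' Read a chemical descriptor matrix
#'
#' Delimited text with first column `chemical_id` and one column per
#' descriptor. Binary kinds (`maccs`: 166-key structural fingerprints;
#' `btrules`: 208 initial biotransformation-rule triggers) must contain only
#' 0/1; `btrules_prob` (65 predicted rule probabilities) must lie in
#' \[0, 1\].
#' A width differing from the canonical one is accepted with a warning.
#'
#' @param path Path to the delimited descriptor file.
#' @param kind One of `"maccs"`, `"btrules"`, `"btrules_prob"`, `"custom"`.
#' @return A numeric matrix (chemicals x descriptors) with class
#'   `descriptor_matrix` and attribute `kind`.
#' @export
read_descriptor_matrix <- function(path,
                                   kind = c("custom", "maccs", "btrules",
                                            "btrules_prob")) {
  kind <- match.arg(kind)
  df <- .read_delim(path)
  if (!"chemical_id" %in% names(df)) {
    stop_rembench(sprintf("descriptor file '%s' lacks column 'chemical_id'",
                          path),
                  "rembench_format_error")
  }
  m <- as.matrix(df[, setdiff(names(df), "chemical_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$chemical_id)
  descriptor_matrix(m, kind)
}

#' @param values Numeric matrix with chemical row names.
#' @rdname read_descriptor_matrix
#' @export
descriptor_matrix <- function(values, kind = c("custom", "maccs", "btrules",
                                               "btrules_prob")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values) || is.null(rownames(values))) {
    stop_rembench("descriptor values must be a numeric matrix with chemical row names",
                  "rembench_validation_error")
  }
  if (kind %in% c("maccs", "btrules")) {
    bad <- which(values != 0 & values != 1 | !is.finite(values),
                 arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_rembench(
        sprintf("kind '%s' requires binary values; first offending cell: row %s, column %s",
                kind, rownames(values)[bad[1, 1]],
                colnames(values)[bad[1, 2]] %||% bad[1, 2]),
        "rembench_validation_error")
    }
  } else if (kind == "btrules_prob") {
    bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      stop_rembench(
        sprintf("kind 'btrules_prob' requires values in [0, 1]; first offending cell: row %s, column %s",
                rownames(values)[bad[1, 1]],
                colnames(values)[bad[1, 2]] %||% bad[1, 2]),
        "rembench_validation_error")
    }
  }
  expected <- c(maccs = 166L, btrules = 208L, btrules_prob = 65L)
  if (kind %in% names(expected) && ncol(values) != expected[[kind]]) {
    warning(sprintf("descriptor matrix of kind '%s' has %d columns (canonical width is %d)",
                    kind, ncol(values), expected[[kind]]))
  }
  structure(values, kind = kind,
            class = c("descriptor_matrix", class(unclass(values))))
}

#' Read / write a chemical grouping file
#'
#' Two-column delimited text: `chemical_id`, `group` (small integer labels).
#'
#' @param path File path.
#' @export
read_grouping <- function(path) {
  df <- .read_delim(path)
  if (!all(c("chemical_id", "group") %in% names(df))) {
    stop_rembench(sprintf("grouping file '%s' needs columns chemical_id, group",
                          path),
                  "rembench_format_error")
  }
  grp <- as.integer(df$group)
  names(grp) <- as.character(df$chemical_id)
  group_assignment(grp, method = "file")
}

#' @param grouping A `group_assignment` (named integer vector).
#' @rdname read_grouping
#' @export
write_grouping <- function(grouping, path) {
  df <- data.frame(chemical_id = names(grouping),
                   group = as.integer(grouping),
                   stringsAsFactors = FALSE)
  df <- df[order(df$chemical_id), , drop = FALSE]
  .write_delim(df, path)
  invisible(path)
}

#' Write a benchmarking report
#'
#' Emits (a) a per-chemical delimited table (`chemical_id`, `group`,
#' `benchmark_id`, `n_sites`, `n_gap_filled`, `stddev_before`,
#' `stddev_after`, `rem`) at full double precision and (b) a machine-readable
#' JSON summary (median REM, fraction of chemicals with REM > 0, fold-factor
#' equivalents, per-group benchmark choices). Rows are sorted by chemical_id
#' so repeated runs are byte-identical.
#'
#' @param result A `benchmark_result` from [run_ubm()], [run_gbm()] or
#'   [run_toc()].
#' @param path Path for the per-chemical table.
#' @param summary_path Path for the JSON summary; default `<path>.summary.json`.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(result, path,
                                   summary_path = paste0(path, ".summary.json")) {
  pc <- result$per_chemical
  pc <- pc[order(pc$chemical_id), , drop = FALSE]
  out <- pc
  for (col in c("stddev_before", "stddev_after", "rem")) {
    out[[col]] <- sprintf("%.17g", pc[[col]])
  }
  .write_delim(out, path)

  s <- result$summary
  per_group <- NULL
  if (!is.null(s$per_group) && nrow(s$per_group) > 0) {
    pg <- s$per_group[order(s$per_group$group), , drop = FALSE]
    per_group <- lapply(seq_len(nrow(pg)), function(i) {
      list(group = pg$group[i], benchmark_id = pg$benchmark_id[i],
           n_chemicals = pg$n_chemicals[i], median_rem = pg$median_rem[i])
    })
  }
  jsonlite::write_json(
    list(mode = result$mode,
         n_chemicals = nrow(pc),
         median_rem = if (nrow(pc) > 0) s$median_rem else NULL,
         median_fold_factor = if (nrow(pc) > 0) s$median_fold_factor else NULL,
         fraction_rem_positive = if (nrow(pc) > 0) s$fraction_rem_positive else NULL,
         per_group = per_group),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read back the per-chemical table written by [write_benchmark_report()]
#'
#' @param path Path to the per-chemical table.
#' @return A data.frame with the numeric columns restored.
#' @export
read_benchmark_report <- function(path) {
  df <- .read_delim(path)
  for (col in c("stddev_before", "stddev_after", "rem")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}
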