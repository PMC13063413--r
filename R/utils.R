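# internal helpers shared across modules

stop_rembench <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rembench_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# delimiter by file extension; .tsv/.txt -> tab, everything else comma
.delim_for <- function(path) {
  if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
}

.read_delim <- function(path) {
  if (!file.exists(path)) {
    stop_rembench(sprintf("file not found: '%s'", path), "rembench_io_error")
  }
  utils::read.table(path, header = TRUE, sep = .delim_for(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""), comment.char = "",
                    quote = "\"")
}

.write_delim <- function(df, path) {
  utils::write.table(df, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE, na = "")
}
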