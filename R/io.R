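# Delimited-text I/O. Dialect throughout: comma-separated, UTF-8, "."
# decimal, mandatory header row. Seeds travel with the data as "# key: value"
# comment headers so a written table can be regenerated.

write_with_meta <- function(df, path, meta = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(meta)) {
    writeLines(sprintf("# %s: %s", k, meta[[k]]), con)
  }
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_meta <- function(path) {
  hdr <- readLines(path, n = 50L, encoding = "UTF-8")
  hdr <- hdr[startsWith(hdr, "#")]
  meta <- list()
  for (line in hdr) {
    m <- regmatches(line, regexec("^#\\s*([^:]+):\\s*(.*)$", line))[[1]]
    if (length(m) == 3L) meta[[trimws(m[2])]] <- trimws(m[3])
  }
  meta
}

#' Read and write long-format trial data
#'
#' CSV with columns `region`, `treatment`, `replicate`, `trait`, `value` and
#' an optional `# seed: <int>` comment header; the seed round-trips through
#' the `"seed"` attribute.
#'
#' @param data long-format trial data frame.
#' @param path file path.
#' @return `write_trial_data` returns the path invisibly; `read_trial_data`
#'   returns the validated data frame.
#' @export
write_trial_data <- function(data, path) {
  validate_trial_data(data)
  meta <- NULL
  if (!is.null(attr(data, "seed"))) meta <- list(seed = attr(data, "seed"))
  write_with_meta(
    data[, c("region", "treatment", "replicate", "trait", "value")],
    path, meta)
}

#' @rdname write_trial_data
#' @export
read_trial_data <- function(path) {
  meta <- read_meta(path)
  out <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                         encoding = "UTF-8")
  validate_trial_data(out)
  if (!is.null(meta$seed)) attr(out, "seed") <- as.integer(meta$seed)
  out
}

#' Read and write decision matrices
#'
#' CSV layout: first column `treatment`, remaining columns one per indicator
#' (header row carries the indicator names). Reading requires the matching
#' [indicator_set] (or a config file read via [read_indicator_config]).
#'
#' @param matrix a [decision_matrix].
#' @param path file path.
#' @param indicators an [indicator_set] describing the columns.
#' @return `write_decision_matrix` returns the path invisibly;
#'   `read_decision_matrix` returns a [decision_matrix].
#' @export
write_decision_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "decision_matrix"))
  df <- data.frame(treatment = matrix$treatments,
                   matrix$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_with_meta(df, path)
}

#' @rdname write_decision_matrix
#' @export
read_decision_matrix <- function(path, indicators) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  if (names(df)[1] != "treatment") {
    stop("expected first column 'treatment' in ", path)
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$treatment
  decision_matrix(values, indicators, treatments = df$treatment)
}

#' Read and write indicator configuration
#'
#' YAML with one entry per indicator: `direction`, `weight` and, for
#' interval indicators, `interval: [low, high]`. Weights are serialised at
#' full double precision so a write/read round-trip is bit-exact.
#'
#' @param indicators an [indicator_set].
#' @param path file path.
#' @return `write_indicator_config` returns the path invisibly;
#'   `read_indicator_config` returns an [indicator_set].
#' @export
write_indicator_config <- function(indicators, path) {
  stopifnot(inherits(indicators, "indicator_set"))
  entries <- lapply(seq_len(nrow(indicators)), function(i) {
    e <- list(direction = indicators$direction[i],
              weight = formatC(indicators$weight[i], digits = 17,
                               format = "g"))
    if (indicators$direction[i] == "interval") {
      e$interval <- formatC(c(indicators$interval_low[i],
                              indicators$interval_high[i]),
                            digits = 17, format = "g")
    }
    e
  })
  names(entries) <- indicators$name
  yaml::write_yaml(list(indicators = entries), path)
  invisible(path)
}

#' @rdname write_indicator_config
#' @export
read_indicator_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$indicators)) stop("no 'indicators' section in ", path)
  entries <- cfg$indicators
  nm <- names(entries)
  dir <- vapply(entries, function(e) as.character(e$direction), character(1))
  w <- vapply(entries, function(e) as.numeric(e$weight), numeric(1))
  lo <- vapply(entries, function(e) {
    if (is.null(e$interval)) NA_real_ else as.numeric(e$interval[[1]])
  }, numeric(1))
  hi <- vapply(entries, function(e) {
    if (is.null(e$interval)) NA_real_ else as.numeric(e$interval[[2]])
  }, numeric(1))
  indicator_set(nm, dir, w, lo, hi)
}

#' Write a TOPSIS report table
#'
#' Emits the evaluation in the layout of a published ranking table —
#' columns `treatment`, `d_plus`, `d_minus`, `closeness`, `rank` — with
#' distances and closeness rounded (3 decimals by default). A full-precision
#' companion file (suffix `_raw`) is always written alongside.
#'
#' @param result a `topsis_result` from [run_topsis].
#' @param path output CSV path.
#' @param digits decimals for the rounded report.
#' @return The report path, invisibly.
#' @export
write_topsis_report <- function(result, path, digits = 3) {
  stopifnot(inherits(result, "topsis_result"))
  df <- as.data.frame(result)
  raw_path <- sub("(\\.[^.]+)?$", "_raw\\1", path)
  write_with_meta(df, raw_path)
  rounded <- df
  for (col in c("d_plus", "d_minus", "closeness")) {
    rounded[[col]] <- round(rounded[[col]], digits)
  }
  write_with_meta(rounded, path)
}

#' Read and write sample-by-taxon abundance tables
#'
#' On disk the table follows the common profiler layout — taxa in rows,
#' samples in columns, first column `taxon` — and is transposed to the
#' in-memory samples-by-taxa orientation on reading.
#'
#' @param table abundance matrix, samples in rows.
#' @param path file path.
#' @return `write_taxon_table` returns the path invisibly;
#'   `read_taxon_table` returns a samples-by-taxa numeric matrix.
#' @export
write_taxon_table <- function(table, path) {
  table <- validate_taxon_table(table)
  if (is.null(colnames(table))) {
    colnames(table) <- paste0("taxon", seq_len(ncol(table)))
  }
  df <- data.frame(taxon = colnames(table), t(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- NULL
  if (!is.null(attr(table, "seed"))) meta <- list(seed = attr(table, "seed"))
  write_with_meta(df, path, meta)
}

#' @rdname write_taxon_table
#' @export
read_taxon_table <- function(path) {
  meta <- read_meta(path)
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  if (names(df)[1] != "taxon") stop("expected first column 'taxon' in ", path)
  x <- t(as.matrix(df[, -1, drop = FALSE]))
  colnames(x) <- df$taxon
  x <- validate_taxon_table(x)
  if (!is.null(meta$seed)) attr(x, "seed") <- as.integer(meta$seed)
  x
}
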