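# Shared plumbing: classed errors and the TSV dialect used by all modules
# (UTF-8, tab-separated, header row, '#' comment lines ignored).

cm_stop <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "cleftminer_error", "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

stop_format  <- function(fmt, ...) cm_stop("cleftminer_format_error", fmt, ...)
stop_empty   <- function(fmt, ...) cm_stop("cleftminer_empty_input_error", fmt, ...)
stop_domain  <- function(fmt, ...) cm_stop("cleftminer_domain_error", fmt, ...)
stop_lookup  <- function(fmt, ...) cm_stop("cleftminer_lookup_error", fmt, ...)

cm_read_tsv <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- tryCatch(
    read.delim(path, sep = "\t", header = TRUE, comment.char = "#",
               stringsAsFactors = FALSE, check.names = FALSE, fill = TRUE,
               quote = "", fileEncoding = "UTF-8"),
    error = function(e) stop_format("cannot parse TSV %s: %s", path,
                                    conditionMessage(e)))
  df
}

cm_write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

cm_require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop_format("%s: missing required column(s): %s", path,
                paste(missing, collapse = ", "))
  invisible(df)
}

# comma-joined, sorted representation used for gene lists in output tables
cm_join <- function(x) vapply(x, function(g) paste(sort(unique(g)), collapse = ","),
                              character(1))

cm_split <- function(x) {
  out <- strsplit(as.character(x), ",", fixed = TRUE)
  lapply(out, function(g) g[nzchar(g)])
}

cm_as_probability <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x > 1)
    stop_domain("%s must be a single probability in (0, 1], got %s",
                what, paste(format(x), collapse = ","))
  x
}
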