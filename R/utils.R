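# internal helpers shared across modules

stop_lncnet <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "lncnet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x != trunc(x) || x < min)
    stop_lncnet("lncnet_invalid_parameter", "`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lower || x > upper)
    stop_lncnet("lncnet_invalid_parameter", "`%s` must be a single finite number in [%s, %s]",
                name, format(lower), format(upper))
  as.numeric(x)
}

# Canonical undirected edge key: endpoints sorted lexicographically.
edge_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Write a two-column tab-separated table
#' @noRd
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
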