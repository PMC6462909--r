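#' Build a DEG-restricted PPI network from an edge list
#'
#' Keeps only edges whose two endpoints both belong to `restrict_to` and whose
#' score (when a third column is present) is at least `min_score`. Self-loops
#' and duplicate edges are dropped with logged counts. The node set of the
#' returned graph is the set of edge endpoints: isolated members of
#' `restrict_to` are not added as nodes.
#'
#' @param edge_list A path to a TSV file (`node_a  node_b [score]`, optional
#'   header) or a data frame with those columns.
#' @param restrict_to Character vector of node identifiers to keep (typically
#'   the DEG set). An empty set yields an empty network.
#' @param min_score Minimum edge score (ignored when the edge list is
#'   unscored).
#' @return An undirected simple [igraph::graph] object.
#' @export
build_network <- function(edge_list, restrict_to, min_score = 0) {
  min_score <- assert_number(min_score, "min_score")
  df <- if (is.character(edge_list)) read_edge_list(edge_list) else edge_list
  if (!is.data.frame(df) || ncol(df) < 2L)
    stop_lncnet("lncnet_invalid_input", "edge list needs >= 2 columns")
  a <- trimws(as.character(df[[1]])); b <- trimws(as.character(df[[2]]))
  score <- if (ncol(df) >= 3L) as.numeric(df[[3]]) else rep(Inf, length(a))
  score[is.na(score)] <- -Inf
  restrict_to <- unique(as.character(restrict_to))

  loops <- a == b
  keep <- !loops & a %in% restrict_to & b %in% restrict_to & score >= min_score
  a2 <- pmin(a[keep], b[keep]); b2 <- pmax(a[keep], b[keep])
  dup <- duplicated(edge_key(a2, b2))
  if (any(loops) || any(dup))
    message(sprintf("build_network: dropped %d self-loop(s), %d duplicate edge(s)",
                    sum(loops), sum(dup)))
  el <- cbind(a2[!dup], b2[!dup])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  g
}

#' Read a network edge list from TSV
#'
#' @param path TSV with two node columns and an optional numeric score column;
#'   a header line is detected when the first row's third column (if any) is
#'   non-numeric or the first two fields are `node_a`/`node_b`-style names.
#' @return Data frame with columns `node_a`, `node_b` and optionally `score`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path))
    stop_lncnet("lncnet_io_error", "edge list file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(node_a = character(0), node_b = character(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad))
    stop_lncnet("lncnet_parse_error", "malformed edge-list line %d in %s", bad[1], path)
  first <- fields[[1]]
  has_header <- tolower(first[1]) %in% c("node_a", "source", "from", "protein1")
  if (has_header) fields <- fields[-1]
  if (!length(fields))
    return(data.frame(node_a = character(0), node_b = character(0)))
  m <- do.call(rbind, lapply(fields, function(f) f[1:max(lengths(fields))]))
  out <- data.frame(node_a = m[, 1], node_b = m[, 2], stringsAsFactors = FALSE)
  if (ncol(m) >= 3L) out$score <- as.numeric(m[, 3])
  out
}

#' Node degrees sorted for hub inspection
#'
#' @param net An igraph network.
#' @return Data frame `node`, `degree`, sorted by degree descending, ties by
#'   node identifier ascending.
#' @export
degree_table <- function(net) {
  if (igraph::vcount(net) == 0)
    return(data.frame(node = character(0), degree = integer(0)))
  d <- igraph::degree(net)
  out <- data.frame(node = names(d), degree = as.integer(d), stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label nodes by targeting and module membership
#'
#' Reproduces the three node classes used when visualizing a DEG PPI network
#' against a miRNA target set: not targeted; targeted but outside every module;
#' targeted and inside a module.
#'
#' @param net An igraph network.
#' @param modules A module table from [mcode_find_modules()] (or any data frame
#'   with a `members` list-column).
#' @param targeted Character vector of targeted gene identifiers.
#' @return Data frame `node`, `class` with class one of `"not-targeted"`,
#'   `"targeted-not-in-module"`, `"targeted-in-module"`.
#' @export
annotate_targeted_nodes <- function(net, modules, targeted) {
  nodes <- igraph::V(net)$name
  in_module <- nodes %in% unlist(modules$members)
  is_target <- nodes %in% targeted
  cls <- ifelse(!is_target, "not-targeted",
                ifelse(in_module, "targeted-in-module", "targeted-not-in-module"))
  data.frame(node = nodes, class = cls, stringsAsFactors = FALSE)
}
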