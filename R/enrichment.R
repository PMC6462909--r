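#' Construct a gene-set collection over a universe
#'
#' Sets are restricted to the universe on construction; sets that become empty
#' are dropped with a warning. The universe should be the genes actually
#' measured (the defensible default when the annotation source's own universe
#' is unrecoverable).
#'
#' @param sets Named list of character gene-sets.
#' @param universe Character vector of background gene identifiers.
#' @return A `geneset_collection`: list with `sets` and `universe`.
#' @export
geneset_collection <- function(sets, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe))
    stop_lncnet("lncnet_invalid_parameter", "universe must be non-empty")
  if (is.null(names(sets)) || any(!nzchar(names(sets))) || anyDuplicated(names(sets)))
    stop_lncnet("lncnet_invalid_input", "sets must have unique non-empty names")
  sets <- lapply(sets, function(s) sort(intersect(unique(as.character(s)), universe)))
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("%d set(s) empty after restriction to the universe; dropped",
                    sum(empty)))
    sets <- sets[!empty]
  }
  structure(list(sets = sets, universe = universe), class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("geneset_collection: %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Hypergeometric upper-tail probability
#'
#' The probability of observing at least `k` annotated genes when drawing `n`
#' genes from a universe of `N` containing `K` annotated ones:
#' `P = sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#'
#' @param k Observed overlap (`0 <= k <= min(K, n)`).
#' @param K Annotated-set size (`<= N`).
#' @param n Query size (`<= N`).
#' @param N Universe size.
#' @return Upper-tail p-value; exactly 1 when `k = 0`.
#' @examples
#' hypergeom_upper_tail(3, 4, 5, 10)
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  k <- assert_count(k, "k"); K <- assert_count(K, "K")
  n <- assert_count(n, "n"); N <- assert_count(N, "N", min = 1L)
  if (K > N || n > N || k > min(K, n))
    stop_lncnet("lncnet_invalid_parameter",
                "inconsistent counts: need K <= N, n <= N, k <= min(K, n)")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation test over a collection
#'
#' Tests each set with at least one query gene for over-representation of the
#' query. Query genes outside the universe are dropped with a message. No
#' multiplicity correction is applied by default (the published criterion is a
#' raw hypergeometric p <= 0.05); Benjamini-Hochberg is available via
#' `adjust = "BH"`, in which case the `enriched` flag uses the adjusted value.
#'
#' @param query Character vector of query genes.
#' @param collection A [geneset_collection()].
#' @param alpha Enrichment threshold on the (possibly adjusted) p-value.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Data frame `set_name`, `k`, `K`, `n`, `N`, `p` (and `p_adj` when
#'   `adjust = "BH"`), `enriched`, sorted by p ascending, ties by set name.
#' @export
enrich <- function(query, collection, alpha = 0.05, adjust = c("none", "BH")) {
  stopifnot(inherits(collection, "geneset_collection"))
  adjust <- match.arg(adjust)
  alpha <- assert_number(alpha, "alpha", lower = 0, upper = 1)
  query <- unique(as.character(query))
  outside <- setdiff(query, collection$universe)
  if (length(outside))
    message(sprintf("enrich: %d query gene(s) outside the universe dropped", length(outside)))
  query <- intersect(query, collection$universe)
  N <- length(collection$universe); n <- length(query)

  k <- vapply(collection$sets, function(s) length(intersect(s, query)), integer(1))
  K <- lengths(collection$sets)
  keep <- k >= 1L
  out <- data.frame(set_name = names(collection$sets)[keep],
                    k = unname(k[keep]), K = unname(K[keep]),
                    n = rep(n, sum(keep)), N = rep(N, sum(keep)),
                    stringsAsFactors = FALSE)
  out$p <- vapply(seq_len(nrow(out)), function(i)
    hypergeom_upper_tail(out$k[i], out$K[i], out$n[i], out$N[i]), numeric(1))
  if (adjust == "BH") {
    out$p_adj <- p.adjust(out$p, method = "BH")
    out$enriched <- out$p_adj <= alpha
  } else {
    out$enriched <- out$p <= alpha
  }
  out <- out[order(out$p, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fraction of reference pathways containing at least one query gene
#'
#' The pathway-coverage statistic: of the sets named in `reference_enriched`,
#' the fraction containing at least one gene of `query_genes`.
#'
#' @param reference_enriched Character vector of set names (must exist in the
#'   collection and be non-empty).
#' @param query_genes Character vector of genes.
#' @param collection A [geneset_collection()].
#' @return List with `numerator`, `denominator`, `fraction`.
#' @export
pathway_coverage <- function(reference_enriched, query_genes, collection) {
  stopifnot(inherits(collection, "geneset_collection"))
  reference_enriched <- unique(as.character(reference_enriched))
  if (!length(reference_enriched))
    stop_lncnet("lncnet_undefined_fraction", "reference pathway set is empty")
  missing <- setdiff(reference_enriched, names(collection$sets))
  if (length(missing))
    stop_lncnet("lncnet_invalid_parameter", "unknown reference set(s): %s",
                paste(head(missing, 3), collapse = ", "))
  hit <- vapply(collection$sets[reference_enriched],
                function(s) length(intersect(s, query_genes)) > 0, logical(1))
  list(numerator = sum(hit), denominator = length(reference_enriched),
       fraction = sum(hit) / length(reference_enriched))
}

#' Read / write gene sets in GMT format
#'
#' GMT: one set per line, tab-separated `name<TAB>description<TAB>gene...`.
#'
#' @param path File path.
#' @param universe Universe for the resulting collection; defaults to the
#'   union of all set members.
#' @return `read_gmt` returns a [geneset_collection()]; `write_gmt` its path,
#'   invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path))
    stop_lncnet("lncnet_io_error", "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop_lncnet("lncnet_parse_error", "malformed GMT line %d in %s", bad[1], path)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1)
  if (is.null(universe)) universe <- unique(unlist(sets))
  geneset_collection(sets, universe)
}

#' @rdname read_gmt
#' @param collection A [geneset_collection()] to write.
#' @param descriptions Optional named character vector of set descriptions
#'   (defaults to `"na"`).
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "geneset_collection"))
  nm <- names(collection$sets)
  desc <- if (is.null(descriptions)) rep("na", length(nm)) else descriptions[nm]
  lines <- vapply(seq_along(nm), function(i)
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
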