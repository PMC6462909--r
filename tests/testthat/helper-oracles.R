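# Independent oracles and tiny fixture builders. These deliberately avoid the
# code paths they check: the k-core oracle prunes an edge data frame by hand
# (no igraph), and the hypergeometric oracle enumerates every draw (no phyper).

# all C(n,2) edges of a clique over `ids`
clique_edges <- function(ids) {
  p <- t(combn(ids, 2))
  data.frame(node_a = p[, 1], node_b = p[, 2], stringsAsFactors = FALSE)
}

path_edges <- function(ids) {
  data.frame(node_a = ids[-length(ids)], node_b = ids[-1], stringsAsFactors = FALSE)
}

# TRUE iff the subgraph of `edges` induced by `members` contains a k-core,
# by iterative pruning of nodes with degree < k
has_kcore_oracle <- function(members, edges, k) {
  e <- edges[edges$node_a %in% members & edges$node_b %in% members, , drop = FALSE]
  nodes <- members
  repeat {
    if (!length(nodes)) return(FALSE)
    deg <- table(factor(c(e$node_a, e$node_b), levels = nodes))
    drop <- names(deg)[deg < k]
    if (!length(drop)) return(TRUE)
    nodes <- setdiff(nodes, drop)
    e <- e[e$node_a %in% nodes & e$node_b %in% nodes, , drop = FALSE]
  }
}

# exhaustive-enumeration hypergeometric upper tail: probability that a draw of
# n from N (of which the first K are marked) contains >= k marked elements
hyper_enum_oracle <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- combn(N, n)
  mean(colSums(draws <= K) >= k)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# minimal profiles object for prioritization tests
make_profiles <- function(targets) {
  prof <- data.frame(mirna_id = names(targets), stringsAsFactors = FALSE)
  prof$n_all_targets <- lengths(targets)
  prof$n_deg_targets <- lengths(targets)
  prof$all_targets <- I(unname(targets))
  prof$deg_targets <- I(unname(targets))
  prof$module_hits <- I(rep(list(list()), length(targets)))
  prof$selected <- logical(length(targets))
  structure(prof, dropped = character(0), unmapped = character(0),
            class = c("mirna_profiles", "data.frame"))
}

make_modules <- function(members) {
  out <- data.frame(module_id = seq_along(members),
                    seed_node = vapply(members, `[`, "", 1),
                    score = rep(0, length(members)),
                    n_members = lengths(members))
  out$members <- I(unname(members))
  out
}
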