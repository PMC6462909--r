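# Re-implementation of the MCODE (molecular complex detection) algorithm:
# vertex weighting by the density of the highest k-core of each node's closed
# neighborhood, greedy seed-and-expand module growth under a node score
# cutoff, then haircut and k-core post-processing. All tie-breaks are fixed so
# the output is deterministic: seeds are processed in decreasing weight order
# with ties broken by ascending node identifier, and surviving modules are
# sorted by score descending with ties broken by discovery (seed) order.

#' MCODE vertex weight
#'
#' The weight of node `v` is `k * density` of the highest k-core of the
#' subgraph induced by `v`'s closed neighborhood (v plus its neighbors), where
#' `k` is that core's core number and density is `2E / (n (n - 1))`. Isolated
#' nodes have weight 0.
#'
#' @param net An igraph network.
#' @param v A node identifier present in the network.
#' @return A single numeric weight.
#' @examples
#' g <- igraph::make_full_graph(5)
#' igraph::V(g)$name <- letters[1:5]
#' mcode_vertex_weight(g, "a")  # 4
#' @export
mcode_vertex_weight <- function(net, v) {
  if (!v %in% igraph::V(net)$name)
    stop_lncnet("lncnet_lookup_error", "node '%s' not in network", v)
  unname(mcode_weights(net)[v])
}

# weights for all nodes at once
mcode_weights <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- igraph::adjacent_vertices(net, nodes)
  w <- vapply(seq_along(nodes), function(i) {
    nb <- unique(c(nodes[i], names(adj[[i]])))
    if (length(nb) < 2L) return(0)
    sub <- igraph::induced_subgraph(net, nb)
    cor <- igraph::coreness(sub)
    kmax <- max(cor)
    if (kmax == 0) return(0)
    core <- igraph::induced_subgraph(sub, names(cor)[cor >= kmax])
    n <- igraph::vcount(core)
    kmax * (2 * igraph::ecount(core)) / (n * (n - 1))
  }, numeric(1))
  setNames(w, nodes)
}

#' Detect dense network modules (MCODE)
#'
#' Seeds are unvisited nodes in decreasing weight order. From each seed, a
#' breadth-limited expansion adds unvisited neighbors whose weight is at least
#' `(1 - node_score_cutoff)` times the seed weight; added nodes are marked
#' visited, so modules are disjoint. Each candidate module is post-processed
#' with a haircut (iterative removal of nodes with fewer than two
#' within-module connections) and discarded unless its induced subgraph
#' contains a k-core at `k_core` and retains at least `min_size` members. The
#' module score is `density * size` = `2E / (n - 1)`.
#'
#' @param net An igraph network.
#' @param node_score_cutoff Fractional weight tolerance below the seed weight
#'   for admitting a neighbor (default 0.2).
#' @param k_core Core filter parameter: a surviving module must contain a
#'   k-core at this k (default 4).
#' @param haircut Apply the haircut post-processing step (default `TRUE`).
#' @param fluff Peripheral-node re-addition; not implemented, must stay
#'   `FALSE` (modules are guaranteed disjoint).
#' @param max_depth Maximum expansion depth from the seed (default 100).
#' @param min_size Minimum module size after post-processing (default 3).
#' @return Data frame with columns `module_id`, `seed_node`, `score`,
#'   `n_members` and list-column `members`, sorted by score descending (ties
#'   by seed order), `module_id` numbered 1..k in that order.
#' @export
mcode_find_modules <- function(net, node_score_cutoff = 0.2, k_core = 4,
                               haircut = TRUE, fluff = FALSE,
                               max_depth = 100, min_size = 3) {
  node_score_cutoff <- assert_number(node_score_cutoff, "node_score_cutoff",
                                     lower = 0, upper = 1)
  k_core <- assert_count(k_core, "k_core", min = 2L)
  max_depth <- assert_count(max_depth, "max_depth", min = 1L)
  min_size <- assert_count(min_size, "min_size", min = 1L)
  if (isTRUE(fluff))
    stop_lncnet("lncnet_invalid_parameter", "fluff post-processing is not supported")

  empty <- data.frame(module_id = integer(0), seed_node = character(0),
                      score = numeric(0), n_members = integer(0))
  empty$members <- I(list())
  if (igraph::vcount(net) == 0) return(empty)

  nodes <- igraph::V(net)$name
  w <- mcode_weights(net)
  adj <- lapply(igraph::adjacent_vertices(net, nodes), names)
  names(adj) <- nodes
  order_idx <- order(-w, nodes)
  visited <- setNames(rep(FALSE, length(nodes)), nodes)

  candidates <- list()
  for (seed in nodes[order_idx]) {
    if (visited[seed]) next
    threshold <- (1 - node_score_cutoff) * w[seed]
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- character(0)
      for (u in frontier) {
        for (nb in adj[[u]]) {
          if (!visited[nb] && w[nb] >= threshold) {
            visited[nb] <- TRUE
            members <- c(members, nb)
            nxt <- c(nxt, nb)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    candidates[[length(candidates) + 1L]] <- list(seed = seed, members = members)
  }

  mods <- list()
  for (cand in candidates) {
    members <- cand$members
    if (haircut) members <- haircut_members(net, members)
    if (length(members) < min_size) next
    sub <- igraph::induced_subgraph(net, members)
    if (max(igraph::coreness(sub)) < k_core) next
    n <- length(members)
    score <- if (n > 1) 2 * igraph::ecount(sub) / (n - 1) else 0
    mods[[length(mods) + 1L]] <- list(seed = cand$seed, members = sort(members),
                                      score = score)
  }
  if (!length(mods)) return(empty)

  score <- vapply(mods, `[[`, numeric(1), "score")
  ord <- order(-score, seq_along(mods))
  mods <- mods[ord]
  out <- data.frame(
    module_id = seq_along(mods),
    seed_node = vapply(mods, `[[`, "", "seed"),
    score = vapply(mods, `[[`, numeric(1), "score"),
    n_members = vapply(mods, function(m) length(m$members), integer(1)),
    stringsAsFactors = FALSE
  )
  out$members <- I(lapply(mods, `[[`, "members"))
  out
}

# iteratively remove members with < 2 connections inside the module
haircut_members <- function(net, members) {
  repeat {
    if (length(members) < 2L) return(character(0))
    sub <- igraph::induced_subgraph(net, members)
    deg <- igraph::degree(sub)
    drop <- names(deg)[deg < 2]
    if (!length(drop)) return(members)
    members <- setdiff(members, drop)
  }
}

#' Write a module table to TSV
#' @param modules Module table from [mcode_find_modules()].
#' @param path Output path.
#' @export
write_modules <- function(modules, path) {
  write_tsv(data.frame(
    module_id = modules$module_id,
    score = modules$score,
    seed_node = modules$seed_node,
    members = vapply(modules$members, paste, "", collapse = ","),
    stringsAsFactors = FALSE
  ), path)
}

#' Read a module table written by [write_modules()]
#' @param path TSV path.
#' @return Module table with a `members` list-column.
#' @export
read_modules <- function(path) {
  df <- read_tsv(path)
  df$members <- I(strsplit(df$members, ",", fixed = TRUE))
  df
}
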