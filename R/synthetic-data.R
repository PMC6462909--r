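# Synthetic-data generators. Each generator states the world the pipeline is
# validated in: independent Gaussian log2 intensities with a planted mean shift
# (matching the equal-variance t test's assumptions), Erdos-Renyi PPI
# background with planted dense blocks, driver/decoy miRNA target maps, and
# gene-set collections with planted over-representation. Every planted fact is
# recorded in a `truth` list so recovery tests need no hidden state.

#' Generate a two-group log2 expression matrix with planted effects
#'
#' Emulates a normalized two-group microarray experiment: per-gene baseline
#' means drawn uniformly on \[6, 12\] log2 units, i.i.d. Gaussian noise, and a
#' mean shift of `+/- effect_log2` in the case group for `n_de` randomly chosen
#' genes (signs alternate up/down and are recorded in the truth).
#'
#' @param n_genes,n_de Total genes and number of planted differentially
#'   expressed genes (`n_de <= n_genes`).
#' @param n_case,n_ctrl Samples per group (each >= 2).
#' @param effect_log2 Planted absolute log2 mean shift (> 0).
#' @param noise_sd Gaussian noise standard deviation in log2 units (> 0).
#' @param seed Integer seed; identical seed and parameters give a bit-identical
#'   matrix.
#' @return List with `expr` (an [expression_matrix()]) and `truth` (list with
#'   `de_genes`, a character vector, and `de_signs`, named +/-1 per DE gene).
#' @examples
#' sim <- generate_expression(200, 10, 5, 5, seed = 1)
#' length(sim$truth$de_genes)
#' @export
generate_expression <- function(n_genes, n_de, n_case = 20, n_ctrl = 20,
                                effect_log2 = 1.2, noise_sd = 0.5, seed = 1) {
  n_genes <- assert_count(n_genes, "n_genes", min = 1L)
  n_de <- assert_count(n_de, "n_de", min = 0L)
  n_case <- assert_count(n_case, "n_case", min = 2L)
  n_ctrl <- assert_count(n_ctrl, "n_ctrl", min = 2L)
  effect_log2 <- assert_number(effect_log2, "effect_log2")
  noise_sd <- assert_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_lncnet("lncnet_invalid_parameter", "`noise_sd` must be > 0")
  if (n_de > 0 && effect_log2 <= 0)
    stop_lncnet("lncnet_invalid_parameter", "`effect_log2` must be > 0")
  if (n_de > n_genes)
    stop_lncnet("lncnet_invalid_parameter", "`n_de` cannot exceed `n_genes`")

  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  sample_ids <- c(sprintf("case_%02d", seq_len(n_case)),
                  sprintf("ctrl_%02d", seq_len(n_ctrl)))
  labels <- c(rep("case", n_case), rep("control", n_ctrl))

  withr::with_seed(seed, {
    base <- runif(n_genes, 6, 12)
    values <- base + matrix(rnorm(n_genes * length(sample_ids), 0, noise_sd),
                            n_genes, length(sample_ids))
    de_idx <- if (n_de > 0) sort(sample.int(n_genes, n_de)) else integer(0)
    signs <- rep_len(c(1, -1), n_de)
    if (n_de > 0)
      values[de_idx, seq_len(n_case)] <-
        values[de_idx, seq_len(n_case)] + signs * effect_log2
  })
  dimnames(values) <- list(gene_ids, sample_ids)

  list(
    expr = expression_matrix(values, labels),
    truth = list(de_genes = gene_ids[de_idx],
                 de_signs = setNames(signs, gene_ids[de_idx]))
  )
}

#' Generate a PPI edge list with planted dense blocks
#'
#' Erdos-Renyi background at edge probability `p_background` with planted
#' high-density blocks on pairwise-disjoint node sets. The emitted edge list is
#' simple (no self-loops, no duplicates) with canonically ordered endpoints.
#'
#' @param n_nodes Number of nodes.
#' @param p_background Background edge probability in `[0, 1]`.
#' @param planted List of planted blocks, each `list(size =, density =)` (or a
#'   length-2 numeric `c(size, density)`); every density must exceed
#'   `p_background`.
#' @param seed Integer seed.
#' @param node_ids Optional character vector of node identifiers (length
#'   `n_nodes`); defaults to `"N0001"...`.
#' @param planted_nodes Optional list of explicit disjoint node-sets to plant
#'   on (overrides the sizes in `planted`; must be subsets of `node_ids`).
#' @return List with `edges` (data frame `node_a`, `node_b`) and `truth`
#'   (list with `planted_modules`, a list of character node-sets).
#' @export
generate_ppi <- function(n_nodes, p_background, planted = list(), seed = 1,
                         node_ids = NULL, planted_nodes = NULL) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 1L)
  p_background <- assert_number(p_background, "p_background", lower = 0, upper = 1)
  planted <- lapply(planted, function(b) {
    if (is.numeric(b) && length(b) == 2L) b <- list(size = b[[1]], density = b[[2]])
    b$size <- assert_count(b$size, "planted size", min = 2L)
    b$density <- assert_number(b$density, "planted density", lower = 0, upper = 1)
    if (b$density <= p_background)
      stop_lncnet("lncnet_invalid_parameter", "planted density must exceed p_background")
    b
  })
  if (is.null(node_ids)) node_ids <- sprintf("N%04d", seq_len(n_nodes))
  if (length(node_ids) != n_nodes || anyDuplicated(node_ids))
    stop_lncnet("lncnet_invalid_parameter", "`node_ids` must be %d unique identifiers", n_nodes)
  sizes <- vapply(planted, `[[`, integer(1), "size")
  if (sum(sizes) > n_nodes)
    stop_lncnet("lncnet_invalid_parameter", "sum of planted sizes exceeds n_nodes")

  withr::with_seed(seed, {
    if (is.null(planted_nodes)) {
      pool <- sample(node_ids)
      planted_nodes <- list()
      off <- 0L
      for (s in sizes) {
        planted_nodes <- c(planted_nodes, list(sort(pool[(off + 1):(off + s)])))
        off <- off + s
      }
    } else {
      planted_nodes <- lapply(planted_nodes, function(m) sort(as.character(m)))
      if (anyDuplicated(unlist(planted_nodes)))
        stop_lncnet("lncnet_invalid_parameter", "planted node-sets must be disjoint")
      if (!all(unlist(planted_nodes) %in% node_ids))
        stop_lncnet("lncnet_invalid_parameter", "planted nodes must be among node_ids")
    }

    pairs_of <- function(ids) {
      n <- length(ids)
      i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
      j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
      data.frame(node_a = ids[i], node_b = ids[j], stringsAsFactors = FALSE)
    }

    edges <- list()
    if (p_background > 0 && n_nodes > 1) {
      bg <- pairs_of(node_ids)
      edges <- c(edges, list(bg[runif(nrow(bg)) < p_background, , drop = FALSE]))
    }
    for (b in seq_along(planted)) {
      bp <- pairs_of(planted_nodes[[b]])
      edges <- c(edges, list(bp[runif(nrow(bp)) < planted[[b]]$density, , drop = FALSE]))
    }
  })
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(node_a = character(0), node_b = character(0))
  # canonical endpoint order, then dedupe (background can re-draw a block edge)
  a <- pmin(edges$node_a, edges$node_b); b <- pmax(edges$node_a, edges$node_b)
  edges <- data.frame(node_a = a, node_b = b, stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edge_key(a, b)) & a != b, , drop = FALSE]
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL

  list(edges = edges, truth = list(planted_modules = planted_nodes))
}

#' Generate lncRNA/miRNA/gene target maps with planted drivers and decoys
#'
#' Constructs the three target maps the integration stage consumes: the
#' lncRNA's annotated miRNAs, the lncRNA's annotated direct gene targets, and a
#' miRNA -> gene map. `n_drivers` miRNAs are planted to satisfy the selection
#' filter (at least `min_deg_targets` DEG targets, spanning at least two
#' modules, with two target genes per spanned module so single-gene detection
#' noise cannot break the span); `n_decoys` miRNAs each violate exactly one
#' recorded criterion.
#'
#' Decoy kinds: `"one_module"` (enough DEG targets, but module genes from a
#' single module), `"few_targets"` (`min_deg_targets - 1` DEG targets spanning
#' two modules), `"no_deg"` (no DEG targets at all; dropped at integration).
#' When fewer than two modules are available all decoys fall back to
#' `"no_deg"`, and `n_drivers` must then be 0.
#'
#' @param deg_genes Character vector of (planted) DEG identifiers.
#' @param modules List of disjoint module node-sets (subsets of `deg_genes`
#'   after intersection; drivers draw their module targets from these).
#' @param n_drivers,n_decoys Numbers of planted drivers and decoys.
#' @param min_deg_targets Filter threshold the drivers must clear (>= 1).
#' @param seed Integer seed.
#' @param non_deg_pool Optional identifiers to use as non-DEG filler targets;
#'   defaults to generated `"decoygene-###"` ids guaranteed outside `deg_genes`.
#' @param n_lnc_genes Number of direct lncRNA gene targets to emit (default 31).
#' @param lncrna_id Identifier of the anchoring lncRNA.
#' @param decoy_kinds Optional character vector of decoy kinds to cycle
#'   through; defaults to all three kinds.
#' @return List with `lnc_mirna`, `lnc_gene`, `mirna_gene` (two-column data
#'   frames `source`/`target`) and `truth` (list with `driver_mirnas` and
#'   `decoy_reasons`, a named character vector).
#' @export
generate_target_maps <- function(deg_genes, modules, n_drivers, n_decoys,
                                 min_deg_targets = 7, seed = 1,
                                 non_deg_pool = NULL, n_lnc_genes = 31,
                                 lncrna_id = "ncRNA00201",
                                 decoy_kinds = c("one_module", "few_targets", "no_deg")) {
  n_drivers <- assert_count(n_drivers, "n_drivers")
  n_decoys <- assert_count(n_decoys, "n_decoys")
  min_deg_targets <- assert_count(min_deg_targets, "min_deg_targets", min = 1L)
  deg_genes <- unique(as.character(deg_genes))
  modules <- lapply(modules, function(m) intersect(as.character(m), deg_genes))
  modules <- Filter(length, modules)
  decoy_kinds <- match.arg(decoy_kinds, several.ok = TRUE)
  if (n_drivers > 0 && length(modules) < 2L)
    stop_lncnet("lncnet_invalid_parameter",
                "driver construction needs >= 2 non-empty modules")
  module_genes <- unique(unlist(modules))
  off_module <- setdiff(deg_genes, module_genes)
  if (is.null(non_deg_pool))
    non_deg_pool <- sprintf("decoygene-%03d", seq_len(max(20L, min_deg_targets + 5L)))
  non_deg_pool <- setdiff(unique(as.character(non_deg_pool)), deg_genes)
  if (length(modules) < 2L) decoy_kinds <- "no_deg"

  mirna_ids <- sprintf("mir-syn-%03d", seq_len(n_drivers + n_decoys))
  drivers <- if (n_drivers > 0) mirna_ids[seq_len(n_drivers)] else character(0)
  decoys <- setdiff(mirna_ids, drivers)

  withr::with_seed(seed, {
    pairs <- list()
    add_pairs <- function(mirna, targets)
      pairs[[length(pairs) + 1L]] <<- data.frame(source = mirna, target = targets,
                                                 stringsAsFactors = FALSE)
    for (mi in drivers) {
      picked <- sample(seq_along(modules), 2L)
      tg <- unlist(lapply(picked, function(k) {
        g <- modules[[k]]
        sample(g, min(2L, length(g)))
      }))
      need <- min_deg_targets + sample.int(4L, 1L) - length(unique(tg))
      extra_pool <- setdiff(deg_genes, tg)
      if (need > 0) tg <- c(tg, sample(extra_pool, min(need, length(extra_pool))))
      tg <- unique(tg)
      if (length(tg) < min_deg_targets)
        stop_lncnet("lncnet_invalid_parameter",
                    "not enough DEG genes to plant a driver with %d targets", min_deg_targets)
      add_pairs(mi, c(tg, sample(non_deg_pool, min(5L, length(non_deg_pool)))))
    }
    reasons <- character(0)
    for (i in seq_along(decoys)) {
      kind <- decoy_kinds[((i - 1L) %% length(decoy_kinds)) + 1L]
      if (kind == "one_module") {
        g <- modules[[sample(seq_along(modules), 1L)]]
        tg <- sample(g, min(2L, length(g)))
        need <- min_deg_targets + 2L - length(tg)
        if (need > length(off_module))
          stop_lncnet("lncnet_invalid_parameter",
                      "not enough off-module DEG genes for a one-module decoy")
        tg <- unique(c(tg, sample(off_module, need)))
      } else if (kind == "few_targets") {
        if (min_deg_targets < 3L)
          stop_lncnet("lncnet_invalid_parameter",
                      "few_targets decoys need min_deg_targets >= 3")
        tg <- unlist(lapply(sample(seq_along(modules), 2L),
                            function(k) sample(modules[[k]], 1L)))
        pool <- setdiff(deg_genes, tg)
        tg <- unique(c(tg, sample(pool, min_deg_targets - 1L - length(tg))))
      } else { # no_deg
        tg <- sample(non_deg_pool, min(min_deg_targets + 1L, length(non_deg_pool)))
      }
      reasons[decoys[i]] <- kind
      add_pairs(decoys[i], c(tg, sample(non_deg_pool, min(3L, length(non_deg_pool)))))
    }
    lnc_gene_pool <- unique(c(deg_genes, non_deg_pool))
    lnc_genes <- sample(lnc_gene_pool, min(n_lnc_genes, length(lnc_gene_pool)))
  })

  mirna_gene <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(source = character(0), target = character(0))
  mirna_gene <- unique(mirna_gene)
  rownames(mirna_gene) <- NULL

  list(
    lnc_mirna = data.frame(source = rep(lncrna_id, length(mirna_ids)),
                           target = mirna_ids, stringsAsFactors = FALSE),
    lnc_gene = data.frame(source = rep(lncrna_id, length(lnc_genes)),
                          target = lnc_genes, stringsAsFactors = FALSE),
    mirna_gene = mirna_gene,
    truth = list(driver_mirnas = drivers, decoy_reasons = reasons)
  )
}

#' Generate a gene-set collection with planted enrichment
#'
#' `n_enriched` sets draw a deliberate fraction of their members from `query`
#' (over-representation); the remaining sets are uniform samples from the
#' universe.
#'
#' @param universe Character vector of all gene identifiers.
#' @param n_sets Number of sets.
#' @param set_size_range Length-2 integer range of set sizes.
#' @param n_enriched Number of planted enriched sets (`<= n_sets`).
#' @param query Character vector of query genes (subset of `universe`).
#' @param seed Integer seed.
#' @param enrich_frac Fraction of a planted set drawn from `query` (default 0.6).
#' @return List with `collection` (a [geneset_collection()]) and `truth`
#'   (list with `enriched_sets`, character vector of planted set names).
#' @export
generate_genesets <- function(universe, n_sets, set_size_range = c(10, 40),
                              n_enriched, query = character(0), seed = 1,
                              enrich_frac = 0.6) {
  n_sets <- assert_count(n_sets, "n_sets", min = 1L)
  n_enriched <- assert_count(n_enriched, "n_enriched")
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop_lncnet("lncnet_invalid_parameter", "`query` must be a subset of `universe`")
  if (n_enriched > n_sets)
    stop_lncnet("lncnet_invalid_parameter", "`n_enriched` cannot exceed `n_sets`")
  if (n_enriched > 0 && length(query) == 0)
    stop_lncnet("lncnet_invalid_parameter", "planting enrichment needs a non-empty query")
  if (max(set_size_range) > length(universe))
    stop_lncnet("lncnet_invalid_parameter", "set sizes cannot exceed the universe size")
  enrich_frac <- assert_number(enrich_frac, "enrich_frac", lower = 0, upper = 1)

  names_all <- sprintf("PW_%03d", seq_len(n_sets))
  withr::with_seed(seed, {
    size_choices <- seq(set_size_range[1], set_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), n_sets, replace = TRUE)]
    sets <- vector("list", n_sets)
    nonquery <- setdiff(universe, query)
    for (i in seq_len(n_sets)) {
      s <- sizes[i]
      if (i <= n_enriched) {
        nq <- min(length(query), max(1L, round(enrich_frac * s)))
        sets[[i]] <- c(sample(query, nq), sample(nonquery, min(s - nq, length(nonquery))))
      } else {
        sets[[i]] <- sample(universe, s)
      }
      sets[[i]] <- sort(unique(sets[[i]]))
    }
  })
  names(sets) <- names_all
  list(
    collection = geneset_collection(sets, universe),
    truth = list(enriched_sets = names_all[seq_len(n_enriched)])
  )
}

#' Write all simulated inputs of a run to a directory
#'
#' Emits the file formats the pipeline reads: expression + labels TSV, the
#' three target-map TSVs, the PPI edge-list TSV, the GMT collection, and the
#' ground truth as JSON.
#'
#' @param sim A list as assembled by [run_pipeline()]'s simulation stage:
#'   elements `expr`, `ppi_edges`, `maps`, `collection`, `truth`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"), file.path(dir, "labels.tsv"))
  write_tsv(sim$ppi_edges, file.path(dir, "ppi_edges.tsv"))
  write_tsv(sim$maps$lnc_mirna, file.path(dir, "lnc_mirna.tsv"))
  write_tsv(sim$maps$lnc_gene, file.path(dir, "lnc_gene.tsv"))
  write_tsv(sim$maps$mirna_gene, file.path(dir, "mirna_gene.tsv"))
  write_gmt(sim$collection, file.path(dir, "pathways.gmt"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
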