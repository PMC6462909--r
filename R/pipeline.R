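#' Default run configuration
#'
#' The default thresholds mirror the published analysis (fold change 1.5,
#' Bonferroni-adjusted p 0.01, MCODE k-core 4 and node score cutoff 0.2,
#' selection filter 7 DEG targets / 2 modules, enrichment alpha 0.05). The
#' default simulation block states the synthetic world every recovery test
#' runs in: 2000 genes with 80 planted effects of 1.2 log2 units at noise SD
#' 0.5 in a 20 vs 20 design; a 200-node PPI graph at background density 0.02
#' with planted blocks of sizes 8 and 6 at density 0.95 placed on planted DE
#' genes; 5 driver and 6 decoy miRNAs; 50 gene sets of which 10 are planted
#' enriched.
#'
#' @param seed Integer seed driving every stage.
#' @param out_dir Output directory.
#' @return A nested configuration list (class `run_config`).
#' @export
default_config <- function(seed = 1, out_dir = tempfile("lncnet_run_")) {
  structure(list(
    seed = seed,
    out_dir = out_dir,
    thresholds = list(
      fc = 1.5, alpha = 0.01,
      k_core = 4, node_score_cutoff = 0.2,
      min_deg_targets = 7, min_modules = 2,
      enrich_alpha = 0.05
    ),
    simulation = list(
      n_genes = 2000, n_de = 80, n_case = 20, n_ctrl = 20,
      effect_log2 = 1.2, noise_sd = 0.5,
      ppi_nodes = 200, p_background = 0.02,
      planted = list(c(8, 0.95), c(6, 0.95)),
      n_drivers = 5, n_decoys = 6,
      n_sets = 50, n_enriched = 10, set_size_range = c(10, 40),
      lncrna_id = "ncRNA00201"
    ),
    inputs = NULL
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Collects every violation rather than stopping at the first.
#'
#' @param config A configuration list (see [default_config()]).
#' @return Character vector of violations; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  v <- character(0)
  note <- function(msg) v <<- c(v, msg)
  th <- config$thresholds
  if (is.null(config$seed) || !is.numeric(config$seed)) note("seed must be an integer")
  if (is.null(config$out_dir)) note("out_dir is missing")
  if (is.null(th)) note("thresholds block is missing")
  else {
    if (is.null(th$fc) || th$fc < 1) note("fold-change threshold must be >= 1")
    if (is.null(th$alpha) || th$alpha <= 0 || th$alpha > 1) note("alpha must be in (0, 1]")
    if (is.null(th$k_core) || th$k_core < 2) note("k_core must be >= 2")
    if (is.null(th$node_score_cutoff) || th$node_score_cutoff < 0 || th$node_score_cutoff > 1)
      note("node_score_cutoff must be in [0, 1]")
    if (is.null(th$min_deg_targets) || th$min_deg_targets < 1)
      note("min_deg_targets must be >= 1")
    if (is.null(th$min_modules) || th$min_modules < 1) note("min_modules must be >= 1")
    if (is.null(th$enrich_alpha) || th$enrich_alpha <= 0 || th$enrich_alpha > 1)
      note("enrich_alpha must be in (0, 1]")
  }
  has_sim <- !is.null(config$simulation)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    note("exactly one of `simulation` and `inputs` must be present")
  if (has_inputs) {
    required <- c("expression", "labels", "lnc_mirna", "lnc_gene", "mirna_gene",
                  "edges", "gmt")
    for (f in required) {
      p <- config$inputs[[f]]
      if (is.null(p)) note(sprintf("inputs$%s path is missing", f))
      else if (!file.exists(p)) note(sprintf("inputs$%s file not found: %s", f, p))
    }
  }
  if (has_sim) {
    s <- config$simulation
    for (f in c("n_genes", "n_case", "n_ctrl", "effect_log2", "noise_sd",
                "ppi_nodes", "n_sets"))
      if (is.null(s[[f]]) || !is.numeric(s[[f]]) || s[[f]] <= 0)
        note(sprintf("simulation$%s must be a positive number", f))
    if (!is.null(s$n_de) && !is.null(s$n_genes) && s$n_de > s$n_genes)
      note("simulation$n_de cannot exceed n_genes")
    if (!is.null(s$p_background) && (s$p_background < 0 || s$p_background > 1))
      note("simulation$p_background must be in [0, 1]")
  }
  v
}

#' Load a run configuration from YAML or JSON
#'
#' Values present in the file override [default_config()]; everything else
#' keeps its default. A `simulation: null` entry combined with an `inputs`
#' block switches the run to real-input mode.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop_lncnet("lncnet_io_error", "config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_lncnet("lncnet_io_error", "the 'yaml' package is needed for YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  cfg <- unclass(default_config())
  if (!is.null(raw$inputs)) cfg$simulation <- NULL
  for (nm in names(raw)) {
    if (is.list(raw[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], raw[[nm]])
    else cfg[[nm]] <- raw[[nm]]
  }
  if (!is.null(cfg$simulation$planted) && is.matrix(cfg$simulation$planted))
    cfg$simulation$planted <- asplit(cfg$simulation$planted, 1)
  structure(cfg, class = "run_config")
}

# Build every synthetic input of a simulation run. Per-stage seeds are derived
# from the one run seed (small fixed offsets keep them in 32-bit range).
simulate_inputs <- function(config) {
  s <- config$simulation
  seed <- as.integer(config$seed) %% 2000000000L
  ex <- generate_expression(s$n_genes, s$n_de, s$n_case, s$n_ctrl,
                            s$effect_log2, s$noise_sd, seed = seed)
  de <- ex$truth$de_genes
  all_genes <- rownames(ex$expr$values)
  non_de <- setdiff(all_genes, de)

  planted <- s$planted
  sizes <- vapply(planted, function(b) as.integer(b[[1]]), integer(1))
  plantable <- length(de) >= sum(sizes) && length(planted) > 0
  if (!plantable) planted <- list()

  withr::with_seed(seed + 1L, {
    planted_nodes <- NULL
    if (plantable) {
      pool <- sample(de)
      planted_nodes <- list(); off <- 0L
      for (sz in sizes) {
        planted_nodes <- c(planted_nodes, list(sort(pool[(off + 1):(off + sz)])))
        off <- off + sz
      }
    }
    n_extra <- max(0L, as.integer(s$ppi_nodes) - length(de))
    node_ids <- c(de, sample(non_de, min(n_extra, length(non_de))))
  })
  ppi <- generate_ppi(length(node_ids), s$p_background, planted, seed = seed + 2L,
                      node_ids = node_ids, planted_nodes = planted_nodes)

  n_drivers <- s$n_drivers
  if (length(ppi$truth$planted_modules) < 2L && n_drivers > 0) {
    message("simulate_inputs: fewer than 2 plantable modules; forcing n_drivers = 0")
    n_drivers <- 0L
  }
  maps <- generate_target_maps(
    de, ppi$truth$planted_modules, n_drivers, s$n_decoys,
    min_deg_targets = config$thresholds$min_deg_targets,
    seed = seed + 3L, non_deg_pool = non_de, lncrna_id = s$lncrna_id
  )
  n_enriched <- if (length(de)) s$n_enriched else 0L
  gs <- generate_genesets(all_genes, s$n_sets, s$set_size_range, n_enriched,
                          query = de, seed = seed + 4L)
  list(expr = ex$expr, ppi_edges = ppi$edges, maps = maps,
       collection = gs$collection,
       truth = c(ex$truth, ppi$truth, maps$truth, gs$truth))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes differential expression -> target integration -> network module
#' detection -> miRNA prioritization -> enrichment -> pathway coverage, in
#' order, writing every intermediate artifact to `config$out_dir`. Identical
#' configuration and seed produce byte-identical artifacts (the run report
#' additionally carries a timestamp).
#'
#' @param config A `run_config` (see [default_config()] /
#'   [read_run_config()]).
#' @return Invisibly, a list with the run `report` (stage record counts,
#'   version, config echo) and the main result objects (`degs`, `profiles`,
#'   `modules`, `selected`, `module_counts`, `hub_ranks`, `enrichment`,
#'   `coverage`, and `truth` for simulation runs).
#' @export
run_pipeline <- function(config) {
  violations <- validate_config(config)
  if (length(violations))
    stop_lncnet("lncnet_invalid_parameter", "invalid configuration:\n  - %s",
                paste(violations, collapse = "\n  - "))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulation)) {
    sim <- run_stage("simulate", simulate_inputs(config))
    write_simulation(sim, file.path(out, "inputs"))
    expr <- sim$expr
    lnc_mirna <- target_map(sim$maps$lnc_mirna, "lncRNA")
    lnc_gene <- target_map(sim$maps$lnc_gene, "lncRNA")
    mirna_gene <- target_map(sim$maps$mirna_gene, "miRNA")
    edges <- sim$ppi_edges
    collection <- sim$collection
    truth <- sim$truth
  } else {
    inp <- config$inputs
    expr <- run_stage("load", read_expression(inp$expression, inp$labels))
    lnc_mirna <- run_stage("load", load_target_map(inp$lnc_mirna, "lncRNA"))
    lnc_gene <- run_stage("load", load_target_map(inp$lnc_gene, "lncRNA"))
    mirna_gene <- run_stage("load", load_target_map(inp$mirna_gene, "miRNA"))
    edges <- run_stage("load", read_edge_list(inp$edges))
    collection <- run_stage("load", read_gmt(inp$gmt, universe = rownames(expr$values)))
    truth <- NULL
  }
  th <- config$thresholds

  degs <- run_stage("deg", call_degs(expr, th$fc, th$alpha))
  write_tsv(degs, file.path(out, "degs.tsv"))
  deg_genes <- degs$gene_id

  profiles <- run_stage("integrate",
                        build_profiles(unique(lnc_mirna$target), mirna_gene, deg_genes))
  write_profiles(profiles, file.path(out, "profiles.tsv"))
  write_tsv(data.frame(mirna_id = c(attr(profiles, "dropped"), attr(profiles, "unmapped")),
                       reason = c(rep("no-deg-target", length(attr(profiles, "dropped"))),
                                  rep("unmapped", length(attr(profiles, "unmapped"))))),
            file.path(out, "profile_drops.tsv"))
  gene_flags <- flag_gene_targets(unique(lnc_gene$target), deg_genes)
  write_tsv(gene_flags, file.path(out, "lnc_gene_flags.tsv"))

  net <- run_stage("modules", build_network(edges, restrict_to = deg_genes))
  modules <- run_stage("modules",
                       mcode_find_modules(net, th$node_score_cutoff, th$k_core))
  write_modules(modules, file.path(out, "modules.tsv"))
  write_tsv(degree_table(net), file.path(out, "degrees.tsv"))

  profiles <- run_stage("prioritize", fill_module_hits(profiles, modules))
  selected <- run_stage("prioritize",
                        select_mirnas(profiles, selection_criteria(th$min_deg_targets,
                                                                   th$min_modules)))
  write_selected(selected, file.path(out, "selected.tsv"))
  module_counts <- module_targeting_counts(selected)
  write_tsv(module_counts[, c("module_id", "n_mirnas", "n_genes")],
            file.path(out, "module_counts.tsv"))
  hub_ranks <- rank_hub_genes(selected)
  write_tsv(hub_ranks, file.path(out, "hub_ranks.tsv"))

  enrichment <- run_stage("enrich", enrich(deg_genes, collection, th$enrich_alpha))
  write_tsv(enrichment, file.path(out, "enrichment.tsv"))
  reference <- enrichment$set_name[enrichment$enriched]
  modulated_targets <- sort(unique(unlist(profiles$deg_targets)))
  coverage <- if (length(reference)) {
    run_stage("coverage", pathway_coverage(reference, modulated_targets, collection))
  } else list(numerator = 0L, denominator = 0L, fraction = NA_real_)
  jsonlite::write_json(coverage, file.path(out, "coverage.json"),
                       auto_unbox = TRUE, digits = NA)

  report <- list(
    version = as.character(packageVersion("lncnet")),
    generated_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[c("seed", "thresholds")],
    counts = list(
      genes_tested = nrow(expr$values),
      degs = nrow(degs),
      lnc_mirnas = length(unique(lnc_mirna$target)),
      lnc_genes = length(unique(lnc_gene$target)),
      profiles_retained = nrow(profiles),
      profiles_dropped = length(attr(profiles, "dropped")),
      profiles_unmapped = length(attr(profiles, "unmapped")),
      network_nodes = igraph::vcount(net),
      network_edges = igraph::ecount(net),
      modules = nrow(modules),
      selected_mirnas = nrow(selected),
      modulated_targets = length(modulated_targets),
      enriched_sets = length(reference),
      coverage = coverage
    )
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(report = report, degs = degs, profiles = profiles, net = net,
                 modules = modules, selected = selected,
                 module_counts = module_counts, hub_ranks = hub_ranks,
                 enrichment = enrichment, coverage = coverage, truth = truth))
}
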