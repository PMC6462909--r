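test_that("generate_expression plants what it records", {
  expect_length(generate_expression(100, 0, 3, 3, seed = 1)$truth$de_genes, 0)

  # noise-free limit: planted shift equals effect_log2 exactly (up to noise)
  sim <- generate_expression(50, 10, 4, 4, effect_log2 = 1, noise_sd = 1e-6, seed = 3)
  x <- sim$expr$values
  dm <- rowMeans(x[, sim$expr$labels == "case"]) - rowMeans(x[, sim$expr$labels == "control"])
  expect_equal(abs(unname(dm[sim$truth$de_genes])), rep(1, 10), tolerance = 1e-4)
  expect_equal(unname(sign(dm[sim$truth$de_genes])), unname(sim$truth$de_signs))

  # default-scale config: mean |shift| of planted genes within 3 SE of 1.2
  sim <- generate_expression(2000, 80, 20, 20, effect_log2 = 1.2, noise_sd = 0.5, seed = 1)
  x <- sim$expr$values
  dm <- rowMeans(x[, 1:20]) - rowMeans(x[, 21:40])
  shifts <- abs(dm[sim$truth$de_genes])
  se <- 0.5 * sqrt(1 / 20 + 1 / 20) / sqrt(80)
  expect_lt(abs(mean(shifts) - 1.2), 3 * se)

  expect_error(generate_expression(10, 20, 3, 3), class = "lncnet_invalid_parameter")
  expect_error(generate_expression(10, 2, 1, 3), class = "lncnet_invalid_parameter")
  expect_error(generate_expression(10, 2, 3, 3, noise_sd = 0), class = "lncnet_invalid_parameter")
})

test_that("generators are bit-identical across runs with the same seed", {
  a <- generate_expression(100, 10, 3, 3, seed = 9)
  b <- generate_expression(100, 10, 3, 3, seed = 9)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth, b$truth)

  p1 <- generate_ppi(80, 0.05, list(c(6, 0.9)), seed = 4)
  p2 <- generate_ppi(80, 0.05, list(c(6, 0.9)), seed = 4)
  expect_identical(p1, p2)

  m1 <- generate_target_maps(sprintf("G%03d", 1:40),
                             list(sprintf("G%03d", 1:5), sprintf("G%03d", 6:10)),
                             3, 3, seed = 5)
  m2 <- generate_target_maps(sprintf("G%03d", 1:40),
                             list(sprintf("G%03d", 1:5), sprintf("G%03d", 6:10)),
                             3, 3, seed = 5)
  expect_identical(m1, m2)

  g1 <- generate_genesets(sprintf("G%03d", 1:200), 10, c(5, 20), 2,
                          query = sprintf("G%03d", 1:30), seed = 6)
  g2 <- generate_genesets(sprintf("G%03d", 1:200), 10, c(5, 20), 2,
                          query = sprintf("G%03d", 1:30), seed = 6)
  expect_identical(g1, g2)
})

test_that("generate_ppi extremes and planted density are as stated", {
  # pure 5-clique, no background
  p <- generate_ppi(10, 0, list(c(5, 1)), seed = 1)
  expect_equal(nrow(p$edges), 10)
  blk <- p$truth$planted_modules[[1]]
  expect_true(all(p$edges$node_a %in% blk & p$edges$node_b %in% blk))
  expect_false(any(p$edges$node_a == p$edges$node_b))
  expect_false(any(duplicated(p$edges)))

  # nothing planted, no background -> empty edge list
  expect_equal(nrow(generate_ppi(10, 0, list(), seed = 1)$edges), 0)

  # realized density inside planted blocks stays high
  p <- generate_ppi(200, 0.02, list(c(8, 0.95), c(6, 0.95)), seed = 7)
  for (blk in p$truth$planted_modules) {
    inside <- p$edges$node_a %in% blk & p$edges$node_b %in% blk
    dens <- sum(inside) / choose(length(blk), 2)
    expect_gte(dens, 0.7)
  }
  expect_error(generate_ppi(10, 0.5, list(c(5, 0.4))), class = "lncnet_invalid_parameter")
  expect_error(generate_ppi(5, 0, list(c(4, 1), c(4, 1))), class = "lncnet_invalid_parameter")
})

test_that("target maps plant drivers that satisfy the filter and decoys that do not", {
  deg <- sprintf("G%03d", 1:60)
  mods <- list(sprintf("G%03d", 1:8), sprintf("G%03d", 9:14))
  tm <- generate_target_maps(deg, mods, n_drivers = 5, n_decoys = 6,
                             min_deg_targets = 7, seed = 2)
  expect_length(tm$truth$driver_mirnas, 5)
  # recount every claim from the emitted map alone (truth consistency)
  for (mi in tm$truth$driver_mirnas) {
    tg <- tm$mirna_gene$target[tm$mirna_gene$source == mi]
    expect_gte(length(intersect(tg, deg)), 7)
    span <- sum(vapply(mods, function(m) length(intersect(tg, m)) > 0, logical(1)))
    expect_gte(span, 2)
  }
  for (mi in names(tm$truth$decoy_reasons)) {
    tg <- tm$mirna_gene$target[tm$mirna_gene$source == mi]
    n_deg <- length(intersect(tg, deg))
    span <- sum(vapply(mods, function(m) length(intersect(tg, m)) > 0, logical(1)))
    expect_true(n_deg < 7 || span < 2,
                label = sprintf("%s (%s) violates a criterion", mi, tm$truth$decoy_reasons[mi]))
    switch(tm$truth$decoy_reasons[[mi]],
           one_module = { expect_gte(n_deg, 7); expect_lt(span, 2) },
           few_targets = { expect_lt(n_deg, 7); expect_gte(span, 2) },
           no_deg = expect_equal(n_deg, 0))
  }
  # all miRNAs are listed as lncRNA targets
  expect_setequal(tm$lnc_mirna$target,
                  c(tm$truth$driver_mirnas, names(tm$truth$decoy_reasons)))

  # no drivers: nothing satisfies both criteria
  tm0 <- generate_target_maps(deg, mods, 0, 3, min_deg_targets = 7, seed = 3)
  expect_length(tm0$truth$driver_mirnas, 0)
  # impossible construction: a driver needs two modules
  expect_error(generate_target_maps(deg, mods[1], 2, 0, seed = 1),
               class = "lncnet_invalid_parameter")
  # planted negative: a one-module decoy is in the map but not a driver
  tm1 <- generate_target_maps(deg, mods, 0, 1, min_deg_targets = 7, seed = 4,
                              decoy_kinds = "one_module")
  mi <- names(tm1$truth$decoy_reasons)
  expect_true(mi %in% tm1$mirna_gene$source)
  expect_false(mi %in% tm1$truth$driver_mirnas)
})

test_that("generate_genesets plants detectable enrichment and round-trips GMT", {
  universe <- sprintf("G%04d", 1:1000)
  query <- sprintf("G%04d", 1:100)
  gs <- generate_genesets(universe, 8, c(50, 50), 3, query, seed = 5)
  expect_length(gs$truth$enriched_sets, 3)
  for (nm in gs$truth$enriched_sets) {
    s <- gs$collection$sets[[nm]]
    p <- hypergeom_upper_tail(length(intersect(s, query)), length(s),
                              length(query), length(universe))
    expect_lt(p, 1e-6)
  }
  expect_length(generate_genesets(universe, 5, c(10, 20), 0, query, seed = 1)$truth$enriched_sets, 0)
  expect_error(generate_genesets(universe, 5, c(10, 20), 1, query = c("NOPE"), seed = 1),
               class = "lncnet_invalid_parameter")

  gmt <- tempfile(fileext = ".gmt")
  write_gmt(gs$collection, gmt)
  back <- read_gmt(gmt, universe = universe)
  expect_identical(back$sets, gs$collection$sets)
})

test_that("null synthetic data gives uniform raw p-values downstream", {
  sim <- generate_expression(2000, 0, 20, 20, seed = 13)
  st <- de_stats(sim$expr)
  ks <- suppressWarnings(ks.test(st$p_raw, "punif"))
  expect_gt(ks$p.value, 0.01)
})
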