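test_that("signed fold change follows the signed-linear convention", {
  expect_equal(signed_fold_change(5, 5), 1)
  expect_equal(signed_fold_change(6, 5), 2)
  expect_equal(signed_fold_change(5, 6), -2)
  # frozen: 2^0.848 = 1.800004, the magnitude printed for a 0.848-unit drop
  expect_equal(signed_fold_change(5, 5.848), -1.800004, tolerance = 1e-6)
  # vectorized, |fc| >= 1 always
  d <- seq(-3, 3, by = 0.1)
  fc <- signed_fold_change(d, 0)
  expect_true(all(abs(fc) >= 1))
  expect_error(signed_fold_change(NA_real_, 1), class = "lncnet_invalid_input")
})

test_that("unpaired t test matches the pooled-t oracle and handles degeneracy", {
  # frozen from stats::t.test(var.equal = TRUE) computed before the build
  r <- unpaired_t_test(c(2.1, 2.9, 2.5, 2.7), c(1.1, 1.5, 1.3, 0.9))
  expect_equal(r$t, 6.305841447708, tolerance = 1e-10)
  expect_equal(r$df, 6)
  expect_equal(r$p, 7.419000990997e-04, tolerance = 1e-10)

  expect_equal(unpaired_t_test(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, df = 4, p = 1))
  expect_equal(unpaired_t_test(c(1, 2), c(1, 2, 3))$df, 3)

  # property: agrees with stats::t.test on random data
  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    tt <- t.test(x, y, var.equal = TRUE)
    mine <- unpaired_t_test(x, y)
    expect_equal(mine$t, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(mine$p, tt$p.value, tolerance = 1e-12)
    ttw <- t.test(x, y)
    mw <- unpaired_t_test(x, y, welch = TRUE)
    expect_equal(mw$p, ttw$p.value, tolerance = 1e-12)
  }

  expect_error(unpaired_t_test(1, c(1, 2)), class = "lncnet_insufficient_replicates")
  expect_error(unpaired_t_test(c(1, 1), c(2, 2)), class = "lncnet_degenerate_variance")
})

test_that("bonferroni multiplies and caps", {
  expect_equal(bonferroni(0, 1000), 0)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(1e-5, 2000), 0.02)
  expect_error(bonferroni(0.5, 0), class = "lncnet_invalid_parameter")
  expect_error(bonferroni(1.5, 10), class = "lncnet_invalid_parameter")
})

test_that("call_degs applies both inclusive criteria", {
  # deterministic matrix: 10 genes shifted by exactly 1 log2 unit, ~no noise
  sim <- generate_expression(60, 10, 4, 4, effect_log2 = 1, noise_sd = 1e-4, seed = 7)
  degs <- call_degs(sim$expr)
  expect_setequal(degs$gene_id, sim$truth$de_genes)
  expect_equal(degs$gene_id, sort(degs$gene_id))
  expect_true(all(degs$direction == ifelse(degs$fold_change > 0, "up", "down")))
  up <- names(sim$truth$de_signs)[sim$truth$de_signs > 0]
  expect_setequal(degs$gene_id[degs$direction == "up"], up)

  # identical group means everywhere -> no calls
  m <- matrix(rep(5:8, 16), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:16)))
  m <- m + matrix(rnorm(64, sd = 0.1), 4)
  em <- expression_matrix(m, rep(c("case", "control"), each = 8))
  st <- de_stats(em)
  expect_true(all(st$p_raw >= 0 & st$p_raw <= st$p_adj))

  # boundary: |fc| just below threshold is excluded however small p is
  v <- matrix(c(rep(5 + log2(1.49), 10), rep(5, 10)) + rnorm(20, sd = 1e-4),
              nrow = 1, dimnames = list("gA", paste0("s", 1:20)))
  v <- rbind(v, matrix(rnorm(20, 5, 0.3), 1, dimnames = list("gB", NULL)))
  em2 <- expression_matrix(v, rep(c("case", "control"), each = 10))
  st2 <- de_stats(em2)
  expect_lt(st2$p_adj[1], 1e-6)  # overwhelming significance
  expect_false("gA" %in% call_degs(em2)$gene_id)
})

test_that("degenerate-variance genes are flagged, not given p = 0", {
  v <- rbind(gZ = rep(c(7, 5), each = 4),
             gN = rnorm(8, 5, 0.5))
  colnames(v) <- paste0("s", 1:8)
  em <- expression_matrix(v, rep(c("case", "control"), each = 4))
  expect_warning(degs <- call_degs(em), "zero within-group variance")
  expect_false("gZ" %in% degs$gene_id)
  expect_equal(attr(degs, "degenerate")$gene_id, "gZ")
})

test_that("label swap negates fold changes and preserves raw p (antisymmetry)", {
  sim <- generate_expression(200, 20, 5, 6, seed = 11)
  st1 <- de_stats(sim$expr)
  swapped <- expression_matrix(sim$expr$values,
                               ifelse(sim$expr$labels == "case", "control", "case"))
  st2 <- de_stats(swapped)
  expect_equal(st2$fold_change, -st1$fold_change, tolerance = 1e-12)
  expect_equal(st2$p_raw, st1$p_raw, tolerance = 1e-12)
})

test_that("probe collapse keeps the best p per symbol", {
  degs <- data.frame(gene_id = c("p1", "p2", "p3"),
                     fold_change = c(2, -3, 1.6),
                     p_raw = c(0.001, 0.0001, 0.002),
                     p_adj = c(0.01, 0.001, 0.02),
                     direction = c("up", "down", "up"),
                     stringsAsFactors = FALSE)
  out <- collapse_probes(degs, c(p1 = "SYM", p2 = "SYM"))
  expect_equal(nrow(out), 2)
  expect_equal(out$p_raw[out$gene_id == "SYM"], 0.0001)
  expect_true("p3" %in% out$gene_id)
})

test_that("expression matrix round-trips through TSV", {
  sim <- generate_expression(30, 5, 3, 3, seed = 2)
  ep <- tempfile(fileext = ".tsv"); lp <- tempfile(fileext = ".tsv")
  write_expression(sim$expr, ep, lp)
  back <- read_expression(ep, lp)
  expect_equal(back$values, sim$expr$values, tolerance = 1e-12)
  expect_equal(back$labels, sim$expr$labels)
})
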