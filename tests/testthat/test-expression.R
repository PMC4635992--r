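noiseless_ct <- function(levels, reference = "ACTIN") {
  simulate_ct(levels, reference_gene = reference, noise_sd = 0,
              n_reps = 5, seed = 1)
}

test_that("relative expression follows the 2^-dCt scaling", {
  lv <- tibble::tibble(
    gene = c("g1", "g2", "g3"),
    condition = "c",
    level = c(1, 2^-3, 2^2)   # dCt = 0, +3, -2 cycles
  )
  ct <- noiseless_ct(lv)
  re <- relative_expression(ct, scale = 1000)
  got <- setNames(re$rel_expr, re$gene)
  expect_equal(unname(got["g1"]), 1000)
  expect_equal(unname(got["g2"]), 125)
  expect_equal(unname(got["g3"]), 4000)
  expect_equal(re$n_reps, rep(5L, 3))
  expect_equal(re$sd, rep(0, 3))
})

test_that("relative expression is monotone in target and reference Ct", {
  base <- tidyr::expand_grid(gene = c("ref", "g"), condition = "c",
                             replicate = 1:3)
  base$ct <- ifelse(base$gene == "ref", 20, 22)
  v0 <- relative_expression(ct_table(base, "ref"))$rel_expr
  up_t <- base; up_t$ct[up_t$gene == "g"] <- 23
  expect_lt(relative_expression(ct_table(up_t, "ref"))$rel_expr, v0)
  up_r <- base; up_r$ct[up_r$gene == "ref"] <- 21
  expect_gt(relative_expression(ct_table(up_r, "ref"))$rel_expr, v0)
})

test_that("ddCt fold change matches its definition and inverts cleanly", {
  lv <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 2),
    condition = rep(c("ctrl", "test"), 2),
    level = c(1, 1, 2, 4)
  )
  ct <- noiseless_ct(lv)
  expect_equal(ddct_fold_change(ct, "g1", "test", "ctrl"), 1.0)
  expect_equal(ddct_fold_change(ct, "g2", "test", "ctrl"), 2.0)
  # inverse identity on noisy tables
  ctn <- simulate_ct(lv, noise_sd = 0.3, n_reps = 5, seed = 9)
  f1 <- ddct_fold_change(ctn, "g2", "test", "ctrl")
  f2 <- ddct_fold_change(ctn, "g2", "ctrl", "test")
  expect_equal(f1 * f2, 1, tolerance = 1e-9)
})

test_that("ddCt fold equals the ratio of relative expressions (noiseless)", {
  withr::with_seed(15, {
    lv <- tidyr::expand_grid(gene = sprintf("g%d", 1:4),
                             condition = c("a", "b")) |>
      dplyr::mutate(level = 2^stats::runif(8, -3, 3))
  })
  ct <- noiseless_ct(lv)
  re <- relative_expression(ct)
  for (g in unique(lv$gene)) {
    ratio <- re$rel_expr[re$gene == g & re$condition == "b"] /
      re$rel_expr[re$gene == g & re$condition == "a"]
    expect_equal(ddct_fold_change(ct, g, "b", "a"), ratio,
                 tolerance = 1e-9)
  }
})

test_that("the 2x significance rule is boundary-inclusive", {
  expect_equal(significance_flag(c(2, 1.9, 0.4, 0.5, 1)),
               c("up", "unchanged", "down", "down", "unchanged"))
  expect_equal(significance_flag(3, cutoff = 4), "unchanged")
  expect_error(significance_flag(0), "positive")
  expect_error(significance_flag(-2), "positive")
})

test_that("replicate-level ddCt test flags strong planted folds", {
  lv <- tibble::tibble(gene = "g", condition = c("ctrl", "test"),
                       level = c(1, 8))
  ct <- simulate_ct(lv, noise_sd = 0.2, n_reps = 5, seed = 3)
  res <- ddct_test(ct, "g", "test", "ctrl")
  expect_gt(res$fold, 4)
  expect_lt(res$p_value, 0.05)
})

test_that("heatmap rows are log2, max-anchored at zero", {
  expr <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    condition = rep(c("a", "b", "c"), 2),
    rel_expr = c(4, 2, 1, 5, 5, 5)
  )
  hm <- heatmap_matrix(expr)
  expect_equal(unname(hm["g1", ]), c(0, -1, -2))
  expect_equal(unname(hm["g2", ]), c(0, 0, 0))
  expect_true(all(hm <= 0))
  expect_equal(unname(apply(hm, 1, max)), c(0, 0))
  # zeros replaced by the documented pseudocount
  expr0 <- tibble::tibble(gene = "g", condition = c("a", "b", "c"),
                          rel_expr = c(8, 0, 2))
  expect_message(hm0 <- heatmap_matrix(expr0), "pseudocount")
  expect_equal(unname(hm0[1, ]), c(0, log2(0.002 / 8), -2))
  # all-zero row errors with the gene name
  exprz <- tibble::tibble(gene = "dead", condition = c("a", "b"),
                          rel_expr = c(0, 0))
  expect_error(heatmap_matrix(exprz), "dead")
})

test_that("heatmap rows are invariant to per-row scaling", {
  withr::with_seed(33, {
    expr <- tidyr::expand_grid(gene = sprintf("g%d", 1:4),
                               condition = c("a", "b", "c", "d")) |>
      dplyr::mutate(rel_expr = stats::runif(16, 0.5, 50))
  })
  h1 <- heatmap_matrix(expr)
  scaled <- dplyr::mutate(
    expr, rel_expr = rel_expr * ifelse(gene == "g2", 37, 1)
  )
  h2 <- heatmap_matrix(scaled)
  expect_equal(h1, h2, tolerance = 1e-12)
  # tidy/autoplot round-trip
  td <- tidy(h1)
  expect_equal(nrow(td), 16)
  expect_s3_class(autoplot(h1), "ggplot")
})

test_that("abundance shares flag dominant categories", {
  expr <- tibble::tibble(
    gene = rep(c("g1", "g2"), each = 3),
    condition = rep(c("male", "female", "hermaphrodite"), 2),
    rel_expr = c(80, 10, 10, 1, 1, 1)
  )
  sh <- abundance_share(expr)
  g1 <- sh[sh$gene == "g1", ]
  expect_equal(g1$share[g1$condition == "male"], 0.8)
  expect_true(g1$dominant[g1$condition == "male"])
  g2 <- sh[sh$gene == "g2", ]
  expect_false(any(g2$dominant))
  expect_error(
    abundance_share(tibble::tibble(gene = "g", condition = c("a", "b"),
                                   rel_expr = c(0, 0))),
    "zero total"
  )
})

test_that("tissue specificity survives the full Ct path", {
  lv <- tibble::tibble(
    gene = rep(c("fruity", "flat"), each = 3),
    condition = rep(c("leaf", "root", "fruit"), 2),
    level = c(0.2, 0.2, 8, 1, 1, 1)
  )
  ct <- simulate_ct(lv, noise_sd = 0.2, n_reps = 5, seed = 19)
  expr <- relative_expression(ct)
  lab <- tissue_specificity(expr)
  expect_equal(lab$label[lab$gene == "fruity"], "fruit-specific")
  expect_true(is.na(lab$label[lab$gene == "flat"]))
})

test_that("planted fold changes propagate through noisy Ct tables", {
  lv <- tibble::tibble(gene = "g", condition = c("ctrl", "test"),
                       level = c(1, 4))
  for (seed in 1:20) {
    ct <- simulate_ct(lv, noise_sd = 0.3, n_reps = 5, seed = seed)
    f <- ddct_fold_change(ct, "g", "test", "ctrl")
    # ddCt estimate sd = 2 * 0.3 / sqrt(5) ~ 0.27 cycles; 3 sd band
    expect_gt(f, 4 * 2^-0.9)
    expect_lt(f, 4 * 2^0.9)
    expect_equal(significance_flag(f), "up")
  }
})
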