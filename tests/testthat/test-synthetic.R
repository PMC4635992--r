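test_that("bundles are pure functions of their seed", {
  b1 <- simulate_arf_family(seed = 2)
  b2 <- simulate_arf_family(seed = 2)
  expect_identical(b1$proteins, b2$proteins)
  expect_identical(b1$cds, b2$cds)
  expect_identical(b1$alignment, b2$alignment)
  expect_identical(b1$promoters, b2$promoters)
  expect_identical(as.data.frame(b1$ct_stage), as.data.frame(b2$ct_stage))
  expect_identical(b1$manifest$motif_hits, b2$manifest$motif_hits)
  b3 <- simulate_arf_family(seed = 3)
  expect_false(identical(b1$proteins$seq, b3$proteins$seq))
})

test_that("written bundles are byte-identical across runs", {
  d1 <- file.path(tempdir(), "bundleA")
  d2 <- file.path(tempdir(), "bundleB")
  simulate_arf_family(seed = 4, dir = d1)
  simulate_arf_family(seed = 4, dir = d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("bundle dimensions follow the requested configuration", {
  b <- simulate_arf_family(n_focal = 11,
                           n_reference = c(At = 23, Os = 25), seed = 1)
  expect_equal(nrow(b$proteins), 11)
  expect_equal(nrow(b$alignment), 59)
  expect_equal(sum(b$species_map$species == "At"), 23)
  expect_equal(sum(b$species_map$species == "Os"), 25)
  expect_equal(nrow(b$promoters), 27)
  expect_equal(nrow(b$manifest$cherries), 7)
  expect_equal(table(b$manifest$categories$category)[["activator"]], 4)
  # CDS length is 3 x protein length throughout
  expect_equal(nchar(b$cds$seq), 3L * nchar(b$proteins$seq))
  expect_error(
    simulate_arf_family(seed = 1, params = list(margin = 1.5)),
    "margin"
  )
})

test_that("zero-length branches leave sequences identical", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0,d:0);")
  aln <- evolve_alignment(tr, "MKLVQQSTR", seed = 5)
  expect_equal(length(unique(aln$seq)), 1L)
  expect_equal(aln$seq[1], "MKLVQQSTR")
  expect_error(evolve_alignment(tr, "", seed = 1), "zero-length")
})

test_that("evolved divergence matches the uniform-replacement expectation", {
  # two leaves separated by total path 0.1, 10,000 sites
  tr <- ape::read.tree(text = "(a:0.05,b:0.05,c:0.05);")
  withr::with_seed(55, root <- random_peptide(10000))
  aln <- evolve_alignment(tr, root, seed = 56)
  d <- pairwise_distance(aln, model = "p_distance")
  t_path <- 0.1
  p_expected <- (19 / 20) * (1 - exp(-t_path * 20 / 19))
  sd3 <- 3 * sqrt(p_expected * (1 - p_expected) / 10000)
  expect_lt(abs(d["a", "b"] - p_expected), sd3)
})

test_that("NJ recovers generating topologies across the usable rate range", {
  fmt <- paste0(
    "(((L1:%g,L2:%g):%g,(L3:%g,L4:%g):%g):%g,",
    "((L5:%g,L6:%g):%g,(L7:%g,L8:%g):%g):%g,",
    "((L9:%g,L10:%g):%g,(L11:%g,L12:%g):%g):%g);"
  )
  for (scale in c(0.05, 0.2, 0.5)) {
    nwk <- gsub("%g", format(scale), fmt, fixed = TRUE)
    tr <- ape::read.tree(text = nwk)
    withr::with_seed(60, root <- random_peptide(800))
    aln <- evolve_alignment(tr, root, seed = 61)
    nj_tree <- neighbor_joining(pairwise_distance(aln, "poisson"))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(nj_tree),
                                           ape::unroot(tr))),
                 0, label = paste("scale", scale))
  }
})

test_that("plant_motifs yields exactly the requested hits", {
  motifs <- aux_motifs("methods")
  pos <- tibble::tibble(motif_id = "AUX1", start = 100L)
  pm <- plant_motifs(1500, motifs, pos, seed = 7)
  expect_equal(nchar(pm$seq), 1500)
  hits <- scan_promoter(tibble::tibble(id = "p", seq = pm$seq), motifs)
  expect_equal(
    paste(hits$motif_id, hits$start, hits$strand),
    paste(pm$hits$motif_id, pm$hits$start, pm$hits$strand)
  )
  expect_true(any(hits$motif_id == "AUX1" & hits$start == 100))

  # count 0: a fully motif-free background
  empty <- plant_motifs(1500, motifs, NULL, seed = 8)
  h0 <- scan_promoter(tibble::tibble(id = "p", seq = empty$seq), motifs)
  expect_equal(nrow(h0), 0)

  expect_error(
    plant_motifs(1500, motifs,
                 tibble::tibble(motif_id = "AUX1", start = 1498L),
                 seed = 1),
    "bounds"
  )
  expect_error(
    plant_motifs(1500, motifs,
                 tibble::tibble(motif_id = c("AUX1", "AUX2"),
                                start = c(10L, 12L)),
                 seed = 1),
    "overlap"
  )
})

test_that("noiseless Ct tables reproduce planted folds exactly", {
  lv <- tibble::tibble(gene = "g", condition = c("c1", "c2"),
                       level = c(1, 2))
  ct <- simulate_ct(lv, noise_sd = 0, n_reps = 3, seed = 1)
  expect_equal(ddct_fold_change(ct, "g", "c2", "c1"), 2.0)
  expect_error(simulate_ct(lv, noise_sd = -1), "noise_sd")
  expect_error(simulate_ct(lv, n_reps = 1), "n_reps")
  expect_error(
    simulate_ct(dplyr::mutate(lv, level = c(1, -2))), "level"
  )
})

test_that("noisy planted folds land in the Gaussian propagation band", {
  lv <- tibble::tibble(gene = "g", condition = c("c1", "c2"),
                       level = c(1, 8))
  inside <- 0L
  for (seed in 1:40) {
    ct <- simulate_ct(lv, noise_sd = 0.2, n_reps = 5, seed = seed)
    f <- ddct_fold_change(ct, "g", "c2", "c1")
    if (f >= 4 && f <= 16) inside <- inside + 1L
  }
  expect_gte(inside, 39L)  # >= 99 % of seeds in expectation
})
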