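# naive per-pair distance oracle (explicit loops)
naive_p_distance <- function(aln) {
  n <- nrow(aln)
  chars <- strsplit(aln$seq, "")
  d <- matrix(0, n, n, dimnames = list(aln$id, aln$id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- chars[[i]]; b <- chars[[j]]
      ok <- a != "-" & b != "-"
      p <- sum(a[ok] != b[ok]) / sum(ok)
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

test_that("p-distance and Poisson correction match hand counts", {
  aln <- toy_alignment()
  d <- pairwise_distance(aln, model = "p_distance")
  expect_equal(unname(d["a", "a"]), 0)
  expect_equal(unname(d["a", "b"]), 0.1)          # 1 mismatch / 10
  expect_equal(unname(d["a", "c"]), 0.5)
  dp <- pairwise_distance(aln, model = "poisson")
  expect_equal(unname(dp["a", "b"]), -log(0.9))   # 0.10536
  expect_equal(unname(dp["a", "b"]), 0.10536, tolerance = 1e-4)
  expect_true(isSymmetric(d))
})

test_that("gapped columns use pairwise deletion, matching the loop oracle", {
  aln <- tibble::tibble(
    id = c("a", "b", "c"),
    seq = c("AC-GTAC-GT", "ACCGA-CAGT", "TTTTT-TTTT")
  )
  d <- pairwise_distance(aln, model = "p_distance")
  expect_equal(d, naive_p_distance(aln))
  withr::with_seed(4, {
    for (i in 1:10) {
      seqs <- replicate(5, paste(sample(c("A", "C", "D", "E", "-"), 40,
                                        replace = TRUE,
                                        prob = c(.3, .3, .15, .15, .1)),
                                 collapse = ""))
      a2 <- tibble::tibble(id = letters[1:5], seq = seqs)
      expect_equal(pairwise_distance(a2, "p_distance"),
                   naive_p_distance(a2))
      dpo <- pairwise_distance(a2, "poisson")
      dpd <- pairwise_distance(a2, "p_distance")
      expect_true(all(dpo >= dpd - 1e-12))
    }
  })
})

test_that("poisson correction errors cleanly at saturation", {
  aln <- tibble::tibble(id = c("a", "b", "c"),
                        seq = c("AAAA", "CCCC", "AACC"))
  expect_error(pairwise_distance(aln, "poisson"), "p_distance")
  expect_no_error(pairwise_distance(aln, "p_distance"))
})

test_that("NJ solves the 3-taxon closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(d)
  expect_equal(sort(tr$tip.label), c("a", "b", "c"))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 4 - 5) / 2)  # 1
  expect_equal(unname(bl["b"]), (3 + 5 - 4) / 2)  # 2
  expect_equal(unname(bl["c"]), (4 + 5 - 3) / 2)  # 3
  expect_error(neighbor_joining(d[1:2, 1:2]), ">= 3")
})

test_that("NJ recovers topology and branch lengths on additive matrices", {
  true <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  d <- additive_matrix(true)
  tr <- neighbor_joining(d)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(true))), 0)
  expect_equal(additive_matrix(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  # random 6-taxon additive matrices re-induce the input exactly
  withr::with_seed(23, {
    for (i in 1:10) {
      t0 <- ape::rtree(6)
      t0$edge.length <- stats::runif(nrow(t0$edge), 0.2, 2)
      d0 <- additive_matrix(t0)
      tr0 <- neighbor_joining(d0)
      expect_equal(additive_matrix(tr0)[rownames(d0), colnames(d0)],
                   d0, tolerance = 1e-8)
    }
  })
})

test_that("NJ attains the zero-residual topology among all topologies", {
  skip_if_not_installed("phangorn")
  withr::with_seed(37, {
    for (n in c(5, 6)) {
      for (i in 1:3) {
        t0 <- ape::rtree(n)
        t0$edge.length <- stats::runif(nrow(t0$edge), 0.3, 2)
        d0 <- additive_matrix(t0)
        nj_tree <- neighbor_joining(d0)
        all_tops <- phangorn::allTrees(n, rooted = FALSE,
                                       tip.label = rownames(d0))
        resid <- vapply(all_tops, ls_residual, numeric(1), d = d0)
        best <- all_tops[[which.min(resid)]]
        expect_lt(min(resid), 1e-12)
        expect_equal(
          as.numeric(ape::dist.topo(ape::unroot(nj_tree),
                                    ape::unroot(best))), 0
        )
        expect_lt(ls_residual(nj_tree, d0), 1e-12)
      }
    }
  })
})

test_that("NJ agrees with an independent implementation off ties", {
  withr::with_seed(51, {
    for (i in 1:5) {
      n <- sample(5:9, 1)
      m <- matrix(stats::runif(n * n, 0.1, 2), n, n)
      d <- (m + t(m)) / 2
      diag(d) <- 0
      dimnames(d) <- list(letters[1:n], letters[1:n])
      mine <- neighbor_joining(d)
      ref <- ape::nj(as.dist(d))
      expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine),
                                             ape::unroot(ref))), 0)
    }
  })
})

test_that("negative branch estimates are clamped to zero with a message", {
  # non-additive matrix whose Saitou-Nei estimates go negative
  d <- matrix(c(0, 0.767, 0.825, 0.263,
                0.767, 0, 0.897, 0.313,
                0.825, 0.897, 0, 0.398,
                0.263, 0.313, 0.398, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  expect_message(tr <- neighbor_joining(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("forced cherries reach full bootstrap support, reproducibly", {
  withr::with_seed(61, {
    twin <- random_peptide(120)
    far1 <- random_peptide(120)
    far2 <- random_peptide(120)
    far3 <- random_peptide(120)
  })
  aln <- tibble::tibble(
    id = c("t1", "t2", "x1", "x2", "x3"),
    seq = c(twin, twin, far1, far2, far3)
  )
  tr <- suppressMessages(
    bootstrap_support(aln, n_reps = 50, seed = 5, model = "p_distance")
  )
  sp <- find_sister_pairs(
    tr, tibble::tibble(leaf = aln$id,
                       species = c("A", "B", "C", "D", "E")),
    min_support = 99
  )
  expect_true(any(sp$leaf_a == "t1" & sp$leaf_b == "t2" &
                    sp$support == 100))
  tr2 <- suppressMessages(
    bootstrap_support(aln, n_reps = 50, seed = 5, model = "p_distance")
  )
  expect_identical(tr$node.label, tr2$node.label)
  sup <- as.numeric(tr$node.label)
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
})

test_that("bootstrap supports are invariant to alignment row order", {
  b <- simulate_arf_family(n_focal = 4, n_reference = c(At = 5, Os = 3),
                           seed = 41, params = list(aln_len = 150))
  aln <- b$alignment
  t1 <- suppressMessages(bootstrap_support(aln, n_reps = 40, seed = 9))
  withr::with_seed(1, perm <- sample(nrow(aln)))
  t2 <- suppressMessages(
    bootstrap_support(aln[perm, ], n_reps = 40, seed = 9)
  )
  s1 <- find_sister_pairs(t1, b$species_map, 0)
  s2 <- find_sister_pairs(t2, b$species_map, 0)
  key <- function(s) paste(pmin(s$leaf_a, s$leaf_b),
                           pmax(s$leaf_a, s$leaf_b))
  expect_setequal(key(s1), key(s2))
})

test_that("simulated 12-taxon cherries recover topology and support", {
  nwk <- paste0(
    "(((A1:0.05,A2:0.05):0.2,(A3:0.05,A4:0.05):0.2):0.1,",
    "((B1:0.05,B2:0.05):0.2,(B3:0.05,B4:0.05):0.2):0.1,",
    "((C1:0.05,C2:0.05):0.2,(C3:0.05,C4:0.05):0.2):0.1);"
  )
  true <- ape::read.tree(text = nwk)
  withr::with_seed(71, root <- random_peptide(400))
  aln <- evolve_alignment(true, root, seed = 72)
  tr <- suppressMessages(bootstrap_support(aln, n_reps = 200, seed = 73))
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(true))), 0)
  smap <- tibble::tibble(leaf = true$tip.label,
                         species = substr(true$tip.label, 1, 1))
  pairs <- find_sister_pairs(tr, smap, min_support = 95)
  # same-species cherries are filtered out; check supports directly
  all_pairs <- find_sister_pairs(
    tr, tibble::tibble(leaf = true$tip.label,
                       species = true$tip.label), # all distinct
    min_support = 95
  )
  key <- paste(pmin(all_pairs$leaf_a, all_pairs$leaf_b),
               pmax(all_pairs$leaf_a, all_pairs$leaf_b))
  expect_true(all(c("A1 A2", "A3 A4", "B1 B2", "B3 B4", "C1 C2",
                    "C3 C4") %in% key))
  expect_equal(nrow(pairs), 0)  # all cherries are within-species
})

test_that("sister-pair detection applies species and support filters", {
  tr <- ape::read.tree(
    text = "((Cp1:1,At1:1)99:1,((Cp2:1,Os1:1)80:1,At2:2):1);"
  )
  smap <- tibble::tibble(leaf = c("Cp1", "At1", "Cp2", "Os1", "At2"),
                         species = c("Cp", "At", "Cp", "Os", "At"))
  sp <- find_sister_pairs(tr, smap, min_support = 99)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$leaf_a, "At1")
  expect_equal(sp$support, 99)
  expect_error(find_sister_pairs(tr, smap[-1, ], 99), "missing")
})

test_that("group labels propagate through homogeneous clades", {
  tr <- ape::read.tree(text = paste0(
    "(((R1:1,F1:1):1,R2:1):1,((R3:1,F2:1):1,(R4:1,F3:1):1):1);"
  ))
  refs <- tibble::tibble(leaf = c("R1", "R2", "R3", "R4"),
                         group = c("I", "I", "II", "III"))
  g <- assign_groups(tr, refs)
  got <- setNames(g$group, g$leaf)
  expect_equal(got[["F1"]], "I")      # inside all-group-I clade
  expect_equal(got[["F2"]], "II")     # cherry with a II reference
  expect_equal(got[["F3"]], "III")
  # leaf sister to a mixed clade is unplaced
  tr2 <- ape::read.tree(text = "((R1:1,R2:1):1,(F1:1,O:1):1);")
  refs2 <- tibble::tibble(leaf = c("R1", "R2"), group = c("I", "II"))
  g2 <- assign_groups(tr2, refs2)
  expect_equal(g2$group[g2$leaf == "F1"], "unplaced")
})
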