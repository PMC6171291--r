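test_that("patristic distances equal explicit path sums", {
  expect_equal(unname(patristic_matrix(read_newick("(A:1,B:2);"))["A", "B"]),
               3)
  tr <- read_newick("((A:1,B:1):2,(C:1,D:1):2);")
  d <- patristic_matrix(tr)
  expect_equal(unname(d["A", "C"]), 6)
  expect_equal(unname(d["A", "B"]), 2)

  set.seed(21)
  for (i in 1:25) {
    t <- ape::rtree(sample(4:15, 1))
    expect_equal(patristic_matrix(t), naive_patristic(t), tolerance = 1e-10)
  }

  t_na <- read_newick("((A:1,B:1):2,C:3);")
  t_na$edge.length[2] <- NA
  expect_error(patristic_matrix(t_na), "missing branch length on edge 2")
})

test_that("patristic matrices satisfy the four-point condition", {
  set.seed(33)
  for (i in 1:10) {
    d <- patristic_matrix(ape::rtree(8))
    labs <- rownames(d)
    for (j in 1:20) {
      q <- sample(labs, 4)
      s <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                  d[q[1], q[3]] + d[q[2], q[4]],
                  d[q[1], q[4]] + d[q[2], q[3]]))
      expect_lt(s[3] - s[2], 1e-9)
    }
  }
})

test_that("matrix averaging is label-aligned and permutation-invariant", {
  set.seed(4)
  a <- rand_dist(6); b <- rand_dist(6)
  expect_equal(average_matrices(list(a, a, a)), a)
  expect_equal(average_matrices(list(a, b))["t01", "t02"],
               (a["t01", "t02"] + b["t01", "t02"]) / 2)
  perm <- sample(rownames(b))
  expect_equal(average_matrices(list(a, b[perm, perm])),
               average_matrices(list(a, b)))
  bad <- b
  rownames(bad)[1] <- colnames(bad)[1] <- "other"
  expect_error(average_matrices(list(a, bad)), "label mismatch")
})

test_that("distance-matrix R-squared matches the direct Pearson formula", {
  set.seed(6)
  a <- rand_dist(6)
  expect_equal(matrix_r2(a, a), 1)
  expect_equal(matrix_r2(a, 2 * a + matrix(1, 6, 6) - diag(6)), 1)
  b <- rand_dist(4, labels = rownames(rand_dist(4)))
  a4 <- rand_dist(4)
  hand <- cor(a4[upper.tri(a4)], b[upper.tri(b)])^2
  expect_equal(matrix_r2(a4, b), hand, tolerance = 1e-12)
  flat <- a; flat[upper.tri(flat)] <- 1; flat[lower.tri(flat)] <- 1
  expect_error(matrix_r2(a, flat), "zero variance")
})

test_that("bipartitions enumerate the non-trivial splits of a tree", {
  q <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  bp <- bipartitions(q)
  expect_equal(length(bp), 1)
  expect_setequal(bp[[1]], c("A", "B"))

  cat5 <- read_newick("((((A:1,B:1):1,C:1):1,D:1):1,E:1);")
  expect_equal(length(bipartitions(cat5)), 2)        # n - 3

  # edge-cut oracle: removing an internal edge splits the leaf set
  set.seed(13)
  for (i in 1:15) {
    t <- ape::rtree(sample(5:12, 1))
    bp <- bipartitions(t)
    keys <- sort(vapply(bp, function(s) paste(sort(s), collapse = "|"),
                        character(1)))
    n <- length(t$tip.label)
    oracle <- c()
    for (e in seq_len(nrow(t$edge))) {
      child <- t$edge[e, 2]
      if (child <= n) next
      below <- ape::extract.clade(t, child)$tip.label
      if (length(below) < 2 || length(below) > n - 2) next
      side <- if (length(below) < n - length(below)) below
      else if (length(below) > n - length(below))
        setdiff(t$tip.label, below)
      else {
        alt <- setdiff(t$tip.label, below)
        if (min(below) < min(alt)) below else alt
      }
      oracle <- c(oracle, paste(sort(side), collapse = "|"))
    }
    expect_identical(keys, sort(unique(oracle)))
  }
})

test_that("Robinson-Foulds distance is the split symmetric difference and a metric", {
  a <- read_newick("((A:1,B:1):1,C:1,(D:1,E:1):1);")
  b <- read_newick("((A:1,C:1):1,B:1,(D:1,E:1):1);")
  expect_equal(robinson_foulds(a, a), 0)
  expect_equal(robinson_foulds(a, b), 2)
  expect_equal(robinson_foulds(b, a), 2)

  set.seed(17)
  trees <- replicate(3, ape::rtree(12, tip.label = sprintf("L%02d", 1:12)),
                     simplify = FALSE)
  # agreement with an independent implementation
  skip_if_not_installed("phangorn")
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(robinson_foulds(trees[[i]], trees[[j]]),
                 phangorn::RF.dist(trees[[i]], trees[[j]]))
  # triangle inequality
  expect_lte(robinson_foulds(trees[[1]], trees[[3]]),
             robinson_foulds(trees[[1]], trees[[2]]) +
               robinson_foulds(trees[[2]], trees[[3]]))
  expect_error(robinson_foulds(a, ape::rtree(4)), "leaf sets")
})

test_that("maximally different caterpillars attain RF = 2(n-3)", {
  n <- 701
  labs <- sprintf("g%03d", 1:n)
  cat_newick <- function(l) {
    s <- paste0("(", l[1], ":1,", l[2], ":1)")
    for (k in 3:length(l)) s <- paste0("(", s, ":1,", l[k], ":1)")
    paste0(s, ";")
  }
  t1 <- read_newick(cat_newick(labs))
  # interleave so that no non-trivial split is shared
  t2 <- read_newick(cat_newick(labs[c(seq(1, n, 2), seq(2, n, 2))]))
  expect_equal(robinson_foulds(t1, t2), 2 * (n - 3))
})

test_that("concordance factors count unrooted clade containment", {
  t1 <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  t2 <- read_newick("((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(concordance_factor(c("A", "B"), list(t1, t1, t1)), 1)
  expect_equal(concordance_factor(c("A", "B"), list(t2, t2)), 0)
  expect_equal(concordance_factor(c("A", "B"), list(t1, t1, t2, t2)), 0.5)
  # the complement names the same split
  expect_equal(concordance_factor(c("C", "D"), list(t1, t2)), 0.5)
  expect_error(concordance_factor("A", list(t1)), "trivial")
  # every clade of the strict consensus has concordance factor 1
  set.seed(9)
  gts <- replicate(4, ape::rtree(8, tip.label = sprintf("L%d", 1:8)),
                   simplify = FALSE)
  cons <- ape::consensus(gts, p = 1)
  for (bp in bipartitions(cons))
    expect_equal(concordance_factor(bp, gts), 1)
})

test_that("Fitch/ACCTRAN gains and losses match the spec'd conventions", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  all1 <- c(A = 1, B = 1, C = 1, D = 1)
  f0 <- fitch_gains_losses(tr, all1)
  expect_equal(f0$total, 0)

  f1 <- fitch_gains_losses(tr, c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(c(f1$gains, f1$losses), c(1, 0))

  # dispersed presence with an ambiguous root resolves to absent
  f2 <- fitch_gains_losses(tr, c(A = 1, B = 0, C = 1, D = 0))
  expect_equal(c(f2$gains, f2$losses), c(2, 0))
  # root-present convention flips the asymmetry
  f2p <- fitch_gains_losses(tr, c(A = 1, B = 0, C = 1, D = 0),
                            root_state = 1L)
  expect_equal(f2p$total, 2)
  expect_gt(f2p$losses, 0)
  expect_error(fitch_gains_losses(tr, c(A = 1, B = 1, C = 0)), "D")
})

test_that("Fitch totals equal the exhaustive ancestral-labeling minimum", {
  set.seed(31)
  for (i in 1:12) {
    n <- sample(4:7, 1)
    tr <- ape::rtree(n)
    for (j in 1:10) {
      states <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
      f <- fitch_gains_losses(tr, states)
      expect_equal(f$total, exhaustive_min_changes(tr, states))
      expect_equal(f$gains + f$losses, f$total)
      expect_equal(sum(f$per_branch$gains), f$gains)
      expect_equal(sum(f$per_branch$losses), f$losses)
    }
  }
})

test_that("pan-genome mapping sums per-cluster Fitch changes over pan columns", {
  tr <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  m_all <- matrix(1L, 4, 3, dimnames = list(c("A", "B", "C", "D"),
                                            paste0("c", 1:3)))
  expect_equal(map_pan_genome(tr, m_all)$total, 0)

  m1 <- m_all
  m1[, 2] <- c(1L, 1L, 0L, 0L)          # one gain
  m1[, 3] <- c(1L, 0L, 1L, 0L)          # two gains
  gl <- map_pan_genome(tr, m1)
  expect_equal(gl$gains, 3)
  expect_equal(gl$losses, 0)
  expect_equal(gl$branch_count, 2 * 4 - 3)
  expect_equal(unname(gl$per_branch_average["gains"]), 3 / 5)
  # singleton columns are not part of the pan-genome
  m2 <- m_all
  m2[, 2] <- c(1L, 0L, 0L, 0L)
  expect_equal(map_pan_genome(tr, m2)$clusters_used, 0)
  expect_error(map_pan_genome(tr, m_all[1:3, ]), "differ")
})
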