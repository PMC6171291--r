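pair_df <- function(...) {
  rows <- list(...)
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(genome_a = pmin(r[[1]], r[[2]]),
               genome_b = pmax(r[[1]], r[[2]]),
               ani = r[[3]], af = r[[4]], stringsAsFactors = FALSE)))
  out[order(out$genome_a, out$genome_b), ]
}

full_pairs <- function(d, ani_fun, af_fun) {
  labs <- rownames(d)
  rows <- list()
  for (i in seq_len(nrow(d) - 1)) for (j in (i + 1):nrow(d))
    rows[[length(rows) + 1L]] <- list(labs[i], labs[j],
                                      ani_fun(d[i, j]), af_fun(d[i, j]))
  do.call(pair_df, rows)
}

test_that("the joint ANI/AF threshold is an inclusive conjunction", {
  p <- pair_df(list("A", "B", 96.5, 0.60), list("A", "C", 97, 0.59),
               list("B", "C", 96.4, 0.80))
  cfg <- analysis_config()
  expect_true(pair_meets_threshold("A", "B", p, cfg))    # both at boundary
  expect_false(pair_meets_threshold("A", "C", p, cfg))   # AF fails
  expect_false(pair_meets_threshold("B", "C", p, cfg))   # ANI fails
  expect_warning(miss <- pair_meets_threshold("A", "Z", p, cfg), "absent")
  expect_false(miss)
})

test_that("species are the largest exclusive threshold-satisfying clades", {
  d <- matrix(5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 1
  good <- function(x) if (x < 2) 99 else 90
  p <- full_pairs(d, good, function(x) if (x < 2) 0.9 else 0.3)
  for (lk in c("single", "complete")) {
    part <- delimit_species(d, p, analysis_config(linkage = lk))
    expect_setequal(vapply(part$species, paste, character(1), collapse = ";"),
                    c("A;B", "C;D"))
  }

  # all pairs below threshold: everything becomes a singleton
  pbad <- full_pairs(d, function(x) 90, function(x) 0.3)
  partb <- delimit_species(d, pbad, analysis_config())
  expect_equal(summarize_partition(partb)$n_singletons, 4)
})

test_that("complete linkage descends where a chained clade passes single linkage", {
  d <- matrix(5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  # exclusive 3-clade {A,B,C}: A-B and B-C meet the threshold, A-C does not
  d["A", "B"] <- d["B", "A"] <- 1
  d["A", "C"] <- d["C", "A"] <- 2
  d["B", "C"] <- d["C", "B"] <- 2
  p <- pair_df(list("A", "B", 99, 0.9), list("B", "C", 99, 0.9),
               list("A", "C", 95, 0.9), list("A", "D", 80, 0.1),
               list("B", "D", 80, 0.1), list("C", "D", 80, 0.1))
  single <- delimit_species(d, p, analysis_config(linkage = "single"))
  expect_setequal(
    vapply(single$species, paste, character(1), collapse = ";"),
    c("A;B;C", "D"))
  complete <- delimit_species(d, p, analysis_config(linkage = "complete"))
  sp_c <- vapply(complete$species, paste, character(1), collapse = ";")
  expect_true("A;B" %in% sp_c)                  # resolution descends
  expect_setequal(sp_c, c("A;B", "C", "D"))
})

test_that("partitions are disjoint covers; complete refines single; thresholds are monotone", {
  set.seed(83)
  for (i in 1:6) {
    sc <- simulate_scenario(small_scenario(seed = 100 + i,
                                           ani_noise_sd = 0.5,
                                           af_noise_sd = 0.05))
    for (lk in c("single", "complete", "single_literal")) {
      part <- delimit_species(sc$avg_matrix, sc$pairs,
                              analysis_config(linkage = lk))
      members <- unlist(part$species)
      expect_identical(sort(members), sort(rownames(sc$avg_matrix)))
      expect_equal(anyDuplicated(members), 0L)
    }
    ps <- delimit_species(sc$avg_matrix, sc$pairs,
                          analysis_config(linkage = "single"))
    pc <- delimit_species(sc$avg_matrix, sc$pairs,
                          analysis_config(linkage = "complete"))
    sing <- lapply(ps$species, sort)
    for (grp in pc$species)
      expect_true(any(vapply(sing, function(s) all(grp %in% s),
                             logical(1))))
    # stricter thresholds never enlarge a species
    hi <- delimit_species(sc$avg_matrix, sc$pairs,
                          analysis_config(ani_min = 99))
    base_of <- setNames(ps$table$size, ps$table$genome)
    hi_of <- setNames(hi$table$size, hi$table$genome)
    expect_true(all(hi_of[names(base_of)] <= base_of))
  }
})

test_that("split reports count threshold-meeting pairs across species", {
  d <- matrix(5, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 1
  d["C", "D"] <- d["D", "C"] <- 1
  p <- full_pairs(d, function(x) if (x < 2) 99 else 90,
                  function(x) if (x < 2) 0.9 else 0.3)
  part <- delimit_species(d, p, analysis_config())
  rep0 <- split_report(part, p, analysis_config())
  expect_equal(rep0$n_meeting, 2)
  expect_equal(rep0$ratio, 0)

  # force one meeting pair across two species
  p2 <- p
  p2[p2$genome_a == "B" & p2$genome_b == "C", c("ani", "af")] <-
    list(99, 0.9)
  part2 <- delimit_species(d, p2, analysis_config(linkage = "complete"))
  rep2 <- split_report(part2, p2, analysis_config())
  expect_equal(rep2$n_meeting, 3)
  expect_equal(rep2$n_split, 1)
  expect_equal(rep2$ratio, 1 / 3)
})

test_that("partition summaries report counts, singletons and sizes", {
  part <- structure(list(species = list("a", "b", "c")), class = "species_partition")
  s <- summarize_partition(part)
  expect_equal(unlist(s[c("n_species", "n_singletons", "largest")]),
               c(n_species = 3, n_singletons = 3, largest = 1))
  part2 <- structure(list(species = list(c("a", "b", "c"), "d")),
                     class = "species_partition")
  s2 <- summarize_partition(part2)
  expect_equal(s2$mean_size, 2)
  expect_equal(s2$largest, 3)
})
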