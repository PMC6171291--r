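test_that("HSSP distance follows the threshold curve in both length regimes", {
  expect_equal(hssp_distance(100, 500), 80.5)
  # continuity at the regime boundary: curve value at L = 450
  v450 <- 100 - 480 * 450^(-0.32 * (1 + exp(-450 / 1000)))
  expect_equal(hssp_distance(100, 450), v450, tolerance = 1e-12)
  expect_lt(abs(v450 - hssp_distance(100, 451)), 0.1)
  # a pid equal to the curve gives distance zero
  curve_at_100 <- 480 * 100^(-0.32 * (1 + exp(-0.1)))
  expect_equal(hssp_distance(curve_at_100, 100), 0, tolerance = 1e-12)
  expect_error(hssp_distance(50, 11), "exceed 11")
})

test_that("global identity matches direct cases and the DP score oracle", {
  expect_equal(global_identity("MKVLAW", "MKVLAW"), 100)
  expect_equal(global_identity("AAAA", "AATA"), 75)
  expect_error(global_identity("", "AA"), "empty")

  # the production aligner's optimum equals an independent affine-gap DP
  set.seed(5)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (i in 1:12) {
    a <- paste(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(4:10, 1), replace = TRUE), collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    expect_equal(Biostrings::score(aln), nw_score_oracle(a, b))
    # identity recomputed from the aligned strings matches the function
    p <- as.character(Biostrings::alignedPattern(aln))
    s <- as.character(Biostrings::alignedSubject(aln))
    expect_equal(Biostrings::score(aln), score_alignment(p, s))
    pv <- strsplit(p, "")[[1]]; sv <- strsplit(s, "")[[1]]
    expect_equal(global_identity(a, b), 100 * sum(pv == sv & pv != "-") /
                   length(pv))
  }
})

make_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(query = r[[1]], subject = r[[2]], pident = as.numeric(r[[3]]),
               length = as.integer(r[[4]]), evalue = as.numeric(r[[5]]),
               bitscore = as.numeric(r[[6]]), qlen = as.integer(r[[7]]),
               slen = as.integer(r[[8]]), query_genome = r[[9]],
               subject_genome = r[[10]], stringsAsFactors = FALSE)))
}

test_that("hit filtering applies the E-value, HSSP and match-length rules", {
  base <- list("p1", "p2", 80, 100, 1e-5, 200, 100, 100, "gA", "gB")
  hits <- make_hits(
    base,
    replace(base, 5, 1e-2),                      # E-value too high
    replace(base, 3, list(30)),                  # HSSP below 20
    replace(base, 4, list(29L)),                 # 29% of shorter seq
    replace(base, c(3, 4), list(99.9, 450L))     # long, passes
  )
  out <- filter_hits(hits, analysis_config())
  expect_equal(nrow(out), 2)
  # boundary: HSSP exactly 20 is retained, 19.9 is not
  curve100 <- 480 * 100^(-0.32 * (1 + exp(-0.1)))
  h2 <- make_hits(replace(base, 3, list(curve100 + 20)),
                  replace(base, 3, list(curve100 + 19.9)))
  expect_equal(nrow(filter_hits(h2, analysis_config())), 1)
  # exactly 30% of the shorter sequence is retained
  h3 <- make_hits(replace(base, 4, list(30L)))
  expect_equal(nrow(filter_hits(h3, analysis_config())), 1)
  # filtering is idempotent and returns a subset
  expect_equal(filter_hits(out, analysis_config()), out)
  # missing lengths are an error naming the record
  h4 <- make_hits(base)
  h4$qlen <- NA_integer_
  expect_error(filter_hits(h4, analysis_config()), "p1")
})

test_that("reciprocal best hits require mutual best edges and are order-invariant", {
  hits <- make_hits(
    list("a1", "b1", 90, 100, 1e-20, 300, 100, 100, "gA", "gB"),
    list("b1", "a1", 90, 100, 1e-20, 300, 100, 100, "gB", "gA"),
    list("a2", "b2", 85, 100, 1e-18, 250, 100, 100, "gA", "gB"),
    list("b2", "a1", 85, 100, 1e-18, 250, 100, 100, "gB", "gA")
  )
  g <- reciprocal_best_hits(hits, analysis_config())
  el <- igraph::as_edgelist(g)
  expect_equal(nrow(el), 1)               # only a1--b1 is mutual
  expect_setequal(as.vector(el), c("a1", "b1"))

  # identity proxy below 60% drops the edge
  hits2 <- make_hits(
    list("a1", "b1", 59, 100, 1e-20, 300, 100, 100, "gA", "gB"),
    list("b1", "a1", 59, 100, 1e-20, 300, 100, 100, "gB", "gA"))
  expect_equal(igraph::ecount(reciprocal_best_hits(hits2,
                                                   analysis_config())), 0)

  # tie on bit score resolved deterministically; stable under shuffles
  tie <- make_hits(
    list("a1", "b1", 90, 100, 1e-20, 300, 100, 100, "gA", "gB"),
    list("a1", "b2", 90, 100, 1e-20, 300, 100, 100, "gA", "gB"),
    list("b1", "a1", 90, 100, 1e-20, 300, 100, 100, "gB", "gA"),
    list("b2", "a1", 90, 100, 1e-20, 300, 100, 100, "gB", "gA"))
  ref <- igraph::as_edgelist(reciprocal_best_hits(tie, analysis_config()))
  set.seed(2)
  for (i in 1:5) {
    shuf <- tie[sample(nrow(tie)), ]
    expect_identical(
      igraph::as_edgelist(reciprocal_best_hits(shuf, analysis_config())),
      ref)
  }
  expect_identical(sort(as.vector(ref)), c("a1", "b1"))  # smallest subject id
})

test_that("MCL clusters respect components and split weakly joined cliques", {
  tri2 <- igraph::make_graph(c("a1", "a2", "a1", "a3", "a2", "a3",
                               "b1", "b2", "b1", "b3", "b2", "b3"),
                             directed = FALSE)
  igraph::E(tri2)$weight <- 1
  cl <- mcl_cluster(tri2, 1.8)
  expect_equal(length(unique(cl$cluster)), 2)
  expect_equal(length(unique(cl$cluster[grepl("^a", cl$protein)])), 1)

  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- paste0("v", 1:4)
  igraph::E(k4)$weight <- 1
  expect_equal(length(unique(mcl_cluster(k4, 1.8)$cluster)), 1)

  # 10-vertex barbell: two 5-cliques joined by one weak edge
  el <- c()
  for (i in 1:4) for (j in (i + 1):5)
    el <- c(el, paste0("x", i), paste0("x", j), paste0("y", i), paste0("y", j))
  barbell <- igraph::make_graph(el, directed = FALSE)
  igraph::E(barbell)$weight <- 1
  barbell <- igraph::add_edges(barbell, c("x1", "y1"), weight = 0.01)
  cl2 <- mcl_cluster(barbell, 1.8)
  expect_equal(length(unique(cl2$cluster)), 2)
  expect_equal(length(unique(cl2$cluster[grepl("^x", cl2$protein)])), 1)
})

test_that("matrix assembly, completeness filtering and core/pan partition do the bookkeeping", {
  clusters <- data.frame(
    protein = c("p1", "p2", "p3", "p4", "p5", "p6"),
    cluster = c("c1", "c1", "c1", "c2", "c2", "c2"),
    genome = c("g1", "g2", "g2", "g1", "g2", "g3"),
    stringsAsFactors = FALSE)
  m <- assemble_matrix(clusters)
  expect_identical(m["g2", "c1"], 2L)
  expect_identical(m["g1", "c2"], 1L)
  # 5 occupied incidences, 4 single-copy
  expect_equal(attr(m, "single_copy_fraction"), 4 / 5)
  expect_warning(assemble_matrix(clusters, genomes = c("g1", "g2", "g3", "g4")),
                 "zero clustered")

  # completeness: reference core of 10, fraction 0.957 -> required 10
  set.seed(1)
  big <- matrix(1L, 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  big["g4", 1:2] <- 0L
  out <- completeness_filter(big, complete_genomes = c("g1", "g2", "g3"),
                             min_fraction = 0.957)
  rep <- attr(out, "report")
  expect_equal(rep$reference_core_size, 10)
  expect_equal(rep$required_count, 10)          # ceil(9.57)
  expect_identical(rownames(out), c("g1", "g2", "g3"))
  expect_identical(rep$dropped, "g4")
  # complete genomes are never dropped at min_fraction <= 1
  expect_true(all(c("g1", "g2", "g3") %in% rownames(out)))

  pp <- core_pan_partition(rbind(
    g1 = c(c1 = 1L, c2 = 1L, c3 = 1L),
    g2 = c(1L, 1L, 0L),
    g3 = c(1L, 0L, 0L)))
  expect_identical(pp$core, "c1")
  expect_setequal(pp$pan, c("c1", "c2"))
  expect_identical(pp$unique, "c3")
  expect_true(all(pp$core %in% pp$pan))
})

test_that("representative choice follows the lexicographic criterion order", {
  expect_identical(choose_representative(c(only = "ACGT")), "only")
  # fewest Ns dominates everything else
  cand <- c(x = "ACGTNNN", y = "ACGTACG")
  expect_identical(choose_representative(cand, peers = c(p = "ACGTACG")), "y")
  # equal Ns: smaller average distance to peers wins
  cand2 <- c(far = "TTTTTTT", near = "ACGTACG")
  expect_identical(choose_representative(cand2, peers = c(p = "ACGTACG")),
                   "near")
  # no peers (criterion ii vacuous): length closest to the median decides
  cand3 <- c(longer = "ACGTACGTAC", fit = "ACGTACGT", short = "ACGTACG")
  expect_identical(choose_representative(cand3), "fit")
})

test_that("gap-rich alignment columns are trimmed at the strict boundary", {
  rows <- c(r1 = "A-C", r2 = "A-C", r3 = "AAC", r4 = "A-C", r5 = "A-C",
            r6 = "A-C", r7 = "A-C", r8 = "A-C", r9 = "A-C", r10 = "A--")
  # column 2: 9/10 gaps (= 0.9, kept); column 3: 1/10 (kept)
  out <- trim_alignment_columns(rows, 0.90)
  expect_identical(unname(nchar(out)), rep(3L, 10))
  rows2 <- sub("C$", "-", rows)                  # column 3 now 10/10 gaps
  out2 <- trim_alignment_columns(rows2, 0.90)
  expect_identical(attr(out2, "kept_columns"), c(1L, 2L))
  expect_error(trim_alignment_columns(c("AC", "A")), "ragged")

  # counting oracle on random alignments
  set.seed(8)
  for (i in 1:20) {
    nr <- sample(3:12, 1); nc <- sample(5:30, 1)
    mat <- matrix(sample(c("A", "C", "G", "T", "-"), nr * nc, TRUE,
                         prob = c(rep(0.15, 4), 0.4)), nr, nc)
    aln <- apply(mat, 1, paste, collapse = "")
    thr <- runif(1, 0.2, 0.9)
    keep_oracle <- which(vapply(seq_len(nc), function(j)
      mean(mat[, j] == "-") <= thr, logical(1)))
    expect_identical(attr(trim_alignment_columns(aln, thr), "kept_columns"),
                     keep_oracle)
  }
})
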