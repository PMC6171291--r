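#' Exclusivity score of a group of genomes
#'
#' The exclusivity score of a group is the minimum distance between any
#' member and any genome outside the group minus the maximum distance
#' between any two members. A positive score means every member is closer
#' to every other member than any member is to any outsider -- the group is
#' exclusive. Singletons have a within-group maximum of zero and are
#' trivially exclusive whenever their score is positive.
#'
#' @param group a nonempty set of labels of `d`; must be a proper subset
#'   unless `permissive`.
#' @param d a labeled distance matrix (typically the genome-wide average
#'   of per-gene patristic distances).
#' @param permissive if `TRUE`, scoring the full label set returns
#'   `min_out = Inf` instead of an error.
#' @return a one-row `data.frame` of class `"exclusivity_record"`:
#'   `members` (labels joined by `;`), `size`, `max_in`, `min_out`,
#'   `score`, `trivial`.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 5, 5, 1, 0, 5, 5, 5, 5, 0, 1, 5, 5, 1, 0), 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' exclusivity_score(c("A", "B"), d)  # max_in 1, min_out 5, score 4
exclusivity_score <- function(group, d, permissive = FALSE) {
  labs <- rownames(d)
  group <- unique(group)
  unknown <- setdiff(group, labs)
  if (length(unknown))
    ex_stop("exclusivity_score: unknown label(s): ",
            paste(head(unknown, 5), collapse = ", "))
  if (!length(group)) ex_stop("exclusivity_score: empty group")
  out <- setdiff(labs, group)
  if (!length(out)) {
    if (!permissive)
      ex_stop("exclusivity_score: group covers all labels; no outside ",
              "genome exists")
    min_out <- Inf
  } else {
    min_out <- min(d[group, out])
  }
  max_in <- if (length(group) == 1L) 0 else max(d[group, group])
  score <- min_out - max_in
  rec <- data.frame(
    members = paste(sort(group), collapse = ";"),
    size = length(group), max_in = max_in, min_out = min_out,
    score = score, trivial = length(group) == 1L,
    stringsAsFactors = FALSE
  )
  class(rec) <- c("exclusivity_record", class(rec))
  rec
}

# score the leaf sets subtended by every internal edge of a rooted tree;
# returns records in preorder of the child node ids
score_tree_clades <- function(tree, d, permissive = FALSE) {
  ntip <- length(tree$tip.label)
  if (!setequal(tree$tip.label, rownames(d)))
    ex_stop("tree leaves and matrix labels differ")
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  nodes <- seq_len(tree$Nnode) + ntip
  root <- nodes[1]
  recs <- lapply(seq_along(pp), function(i) {
    if (nodes[i] == root && length(pp[[i]]) == ntip && !permissive)
      return(NULL)                     # the root clade is unscorable
    cbind(node = nodes[i],
          exclusivity_score(labs[pp[[i]]], d, permissive = permissive))
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Annotate a tree's internal edges with exclusivity scores
#'
#' Every internal edge (an edge whose child is an internal node; the clade
#' of the root itself is the full set and cannot be scored) receives the
#' exclusivity record of its subtended leaf set, evaluated on `d`. The
#' summary counts the internal edges whose score exceeds `-slack`, and the
#' leaves that belong to no non-trivial exclusive group.
#'
#' @param tree a rooted `"phylo"` tree whose tips are the labels of `d`.
#' @param d a labeled distance matrix.
#' @param slack exclusivity slack; a clade counts as exclusive when
#'   `score > -slack`.
#' @return a list of class `"annotated_tree"`: `tree` (with scores as
#'   `node.label`s), `records` (data.frame, one row per internal edge),
#'   and `summary` (list: `n_internal_edges`, `n_exclusive`,
#'   `fraction_exclusive`, `unplaced_leaves`).
#' @export
annotate_tree <- function(tree, d, slack = 0) {
  recs <- score_tree_clades(tree, d)
  ntip <- length(tree$tip.label)
  internal <- recs[recs$size < ntip, , drop = FALSE]  # drop root duplicates
  excl <- internal$score > -slack
  placed <- unique(unlist(strsplit(
    internal$members[excl & internal$size >= 2], ";", fixed = TRUE)))
  tree$node.label <- rep("", tree$Nnode)
  idx <- internal$node - ntip
  tree$node.label[idx] <- sprintf("%.6g", internal$score)
  structure(list(
    tree = tree,
    records = internal,
    summary = list(
      n_internal_edges = nrow(internal),
      n_exclusive = sum(excl),
      fraction_exclusive = if (nrow(internal)) mean(excl) else NA_real_,
      unplaced_leaves = sort(setdiff(tree$tip.label, placed))
    )
  ), class = "annotated_tree")
}

#' @export
print.annotated_tree <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Annotated tree: %d internal edges, %d exclusive (%.1f%%), %d leaves in no non-trivial exclusive group\n",
    s$n_internal_edges, s$n_exclusive, 100 * s$fraction_exclusive,
    length(s$unplaced_leaves)))
  invisible(x)
}

#' Enumerate the exclusive groups of a distance matrix
#'
#' Builds the UPGMA tree of `d` and scores each of its clades. UPGMA is
#' used because every subset with a positive exclusivity score appears as
#' a clade of the UPGMA tree: while such a group is only partly merged, the
#' average distance between any two of its sub-clusters is at most the
#' group's internal maximum, which is strictly below any cluster average
#' involving an outside genome, so the group coalesces completely before
#' joining anything else. At `slack = 0` the non-trivial groups returned
#' are therefore exactly the exclusive subsets of the label set. Singletons
#' are appended and flagged trivially exclusive.
#'
#' @param d a labeled distance matrix.
#' @param slack report clades with `score > -slack`.
#' @return a `data.frame` of exclusivity records (columns as in
#'   [exclusivity_score()], plus `node`, the UPGMA tree node), the UPGMA
#'   result attached as attribute `upgma`.
#' @export
enumerate_exclusive_groups <- function(d, slack = 0) {
  d <- validate_dist_matrix(d)
  up <- upgma(d)
  recs <- score_tree_clades(up$tree, d)
  ntip <- nrow(d)
  recs <- recs[recs$size < ntip, , drop = FALSE]
  keep <- recs[recs$score > -slack, , drop = FALSE]
  singles <- do.call(rbind, lapply(rownames(d), function(l)
    cbind(node = match(l, up$tree$tip.label), exclusivity_score(l, d))))
  out <- rbind(keep, singles)
  rownames(out) <- NULL
  attr(out, "upgma") <- up
  out
}

#' Brute-force enumeration of exclusive groups (test oracle)
#'
#' Scores every nonempty proper subset of the labels and returns those
#' with a strictly positive exclusivity score. Exponential in the number
#' of taxa; refuses more than `guard` taxa.
#'
#' @param d a labeled distance matrix.
#' @param guard maximum taxon count accepted.
#' @return a `data.frame` of exclusivity records.
#' @export
brute_force_exclusive_groups <- function(d, guard = 15) {
  d <- validate_dist_matrix(d)
  n <- nrow(d)
  if (n > guard)
    ex_stop("brute_force_exclusive_groups: refusing n = ", n,
            " (> ", guard, " taxa)")
  labs <- rownames(d)
  bits <- 2^(seq_len(n) - 1)
  recs <- list()
  for (mask in seq_len(2^n - 2)) {
    sel <- bitwAnd(mask, bits) > 0
    max_in <- if (sum(sel) == 1L) 0 else max(d[sel, sel])
    score <- min(d[sel, !sel]) - max_in
    if (score > 0)
      recs[[length(recs) + 1L]] <- exclusivity_score(labs[sel], d)
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    exclusivity_score(labs[1], d)[0, ]
  rownames(out) <- NULL
  out
}

#' Exclusivity-versus-depth profile
#'
#' Describes how exclusivity decays with clade breadth: each non-trivial
#' record contributes a point (`max_in`, `score`), and equal-width bins
#' over `max_in` summarize the points by mean and sample standard
#' deviation (bins holding a single point report the mean only).
#'
#' @param records a `data.frame` of exclusivity records.
#' @param bins number of equal-width bins.
#' @return a list of class `"exclusivity_profile"`: `points` (data.frame
#'   `max_in`, `score`) and `bins` (data.frame `mid`, `n`, `mean`, `sd`).
#' @export
depth_profile <- function(records, bins = 25) {
  pts <- records[!records$trivial, c("max_in", "score"), drop = FALSE]
  if (!nrow(pts)) ex_stop("depth_profile: no non-trivial records")
  rng <- range(pts$max_in)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  idx <- findInterval(pts$max_in, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  bt <- data.frame(
    mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
    n = as.integer(tabulate(idx, nbins = bins)),
    mean = vapply(seq_len(bins), function(b)
      if (any(idx == b)) mean(pts$score[idx == b]) else NA_real_,
      numeric(1)),
    sd = vapply(seq_len(bins), function(b)
      if (sum(idx == b) >= 2) stats::sd(pts$score[idx == b]) else NA_real_,
      numeric(1))
  )
  structure(list(points = pts, bins = bt), class = "exclusivity_profile")
}

#' Exclusivity under genome subsampling
#'
#' Draws random genome subsets of the given sizes, rebuilds the
#' gene-content (Jaccard + UPGMA) tree on each subsample, scores its
#' clades against the corresponding submatrix of the full relatedness
#' matrix, and records the proportion of internal edges that are exclusive
#' and the mean exclusivity score. This probes whether the observed
#' hierarchical structure is an artifact of under-sampling: a flat curve
#' means added genomes disrupt and create exclusive clades at the same
#' rate.
#'
#' @param d_full the full relatedness (average patristic) matrix.
#' @param m the presence/absence matrix over the same genomes.
#' @param sizes subsample sizes (each at most the genome count; sizes
#'   below 4 warn, their clade statistics may be empty).
#' @param replicates replicates per size.
#' @param seed RNG seed; the curve is reproducible given the seed.
#' @param slack exclusivity slack.
#' @return a list of class `"subsample_curve"`: `replicates` (data.frame
#'   `size`, `replicate`, `prop_exclusive`, `mean_score`), `summary`
#'   (per-size mean and sd of both measures), and `seed`.
#' @export
subsample_curve <- function(d_full, m, sizes, replicates = 25, seed = 1,
                            slack = 0) {
  d_full <- validate_dist_matrix(d_full)
  m <- validate_presence_absence(m)
  if (!setequal(rownames(d_full), rownames(m)))
    ex_stop("subsample_curve: matrix genome sets differ")
  genomes <- rownames(d_full)
  if (any(sizes > length(genomes)))
    ex_stop("subsample_curve: size exceeds genome count")
  if (any(sizes < 4))
    ex_warn("subsample_curve: sizes below 4 give empty clade statistics")
  rows <- with_seed(seed, {
    do.call(rbind, lapply(sizes, function(sz) {
      do.call(rbind, lapply(seq_len(replicates), function(r) {
        sub <- sort(sample(genomes, sz))
        ann <- annotate_tree(
          upgma(jaccard_matrix(m[sub, , drop = FALSE]))$tree,
          d_full[sub, sub], slack = slack)
        data.frame(size = sz, replicate = r,
                   prop_exclusive = ann$summary$fraction_exclusive,
                   mean_score = mean(ann$records$score))
      }))
    }))
  })
  summary <- do.call(rbind, lapply(split(rows, rows$size), function(g)
    data.frame(size = g$size[1],
               prop_mean = mean(g$prop_exclusive),
               prop_sd = stats::sd(g$prop_exclusive),
               score_mean = mean(g$mean_score),
               score_sd = stats::sd(g$mean_score))))
  rownames(summary) <- NULL
  structure(list(replicates = rows, summary = summary, seed = seed),
            class = "subsample_curve")
}
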