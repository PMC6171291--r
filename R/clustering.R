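#' UPGMA clustering of a distance matrix
#'
#' Agglomerative average-linkage clustering with proportional
#' (cluster-size weighted) averaging -- classic UPGMA -- or, optionally,
#' unweighted WPGMA averaging. At every step the pair of clusters with the
#' minimal average inter-cluster distance is merged at a height equal to
#' that distance; ties are broken deterministically by the
#' lexicographically smallest member label of the candidate pairs (then the
#' smaller second label), so the result is independent of input order. The
#' returned tree is rooted and ultrametric, with every tip at depth equal
#' to half the final merge height; the cophenetic distance between two tips
#' equals the height at which their lineages merged.
#'
#' @param d a labeled distance matrix (see [validate_dist_matrix()]).
#' @param method `"upgma"` (proportional averaging) or `"wpgma"`.
#' @return a list of class `"upgma"` with elements `tree` (a `"phylo"`)
#'   and `trace` (a data.frame of merges: `a`, `b` -- each cluster named by
#'   its smallest member label -- and `height`, non-decreasing).
#' @export
#' @examples
#' d <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
#' upgma(d)$trace
upgma <- function(d, method = c("upgma", "wpgma")) {
  method <- match.arg(method)
  d <- validate_dist_matrix(d)
  n <- nrow(d)
  if (n < 2) ex_stop("upgma: need at least 2 taxa")
  labs <- rownames(d)
  # active-cluster bookkeeping in hclust conventions:
  # id < 0 : singleton -labs index; id > 0 : row of the merge table
  active <- seq_len(n)
  cl_id <- -seq_len(n)
  cl_size <- rep(1L, n)
  cl_min <- labs                      # smallest member label per cluster
  D <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    sub <- D[active, active, drop = FALSE]
    sub[!upper.tri(sub)] <- Inf
    best <- min(sub)
    cand <- which(sub == best, arr.ind = TRUE)
    # deterministic tie-break on member labels
    l1 <- pmin(cl_min[active[cand[, 1]]], cl_min[active[cand[, 2]]])
    l2 <- pmax(cl_min[active[cand[, 1]]], cl_min[active[cand[, 2]]])
    pick <- order(l1, l2)[1]
    i <- active[cand[pick, 1]]; j <- active[cand[pick, 2]]
    # record the merge (hclust wants singletons first, by convention)
    pair <- sort(c(cl_id[i], cl_id[j]))
    merge[step, ] <- pair
    # UPGMA merge heights are mathematically non-decreasing; absorb only
    # floating-point jitter
    if (step > 1 && best < height[step - 1]) {
      if (height[step - 1] - best > 1e-9 * max(1, height[step - 1]))
        ex_stop("upgma: non-monotone merge heights (internal error)")
      best <- height[step - 1]
    }
    height[step] <- best
    # Lance-Williams update into slot i
    wi <- if (method == "upgma") cl_size[i] / (cl_size[i] + cl_size[j])
    else 0.5
    wj <- 1 - wi
    others <- setdiff(active, c(i, j))
    D[i, others] <- D[others, i] <- wi * D[i, others] + wj * D[j, others]
    cl_size[i] <- cl_size[i] + cl_size[j]
    cl_min[i] <- min(cl_min[i], cl_min[j])
    cl_id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge),
                       labels = labs, method = method),
                  class = "hclust")
  tree <- ape::as.phylo(hc)
  ta <- vapply(seq_len(n - 1L), function(s) {
    id <- merge[s, 1]; if (id < 0) labs[-id] else trace_min(merge, labs, id)
  }, character(1))
  tb <- vapply(seq_len(n - 1L), function(s) {
    id <- merge[s, 2]; if (id < 0) labs[-id] else trace_min(merge, labs, id)
  }, character(1))
  trace <- data.frame(a = pmin(ta, tb), b = pmax(ta, tb),
                      height = height, stringsAsFactors = FALSE)
  structure(list(tree = tree, trace = trace), class = "upgma")
}

# smallest member label of the cluster created at merge row `row`
trace_min <- function(merge, labs, row) {
  stack <- row
  members <- character(0)
  while (length(stack)) {
    id <- stack[1]; stack <- stack[-1]
    if (id < 0) members <- c(members, labs[-id])
    else stack <- c(stack, merge[id, ])
  }
  min(members)
}

# a valid leaf ordering for an hclust object (plotting order; any ordering
# consistent with the merges will do)
hclust_order <- function(merge) {
  walk <- function(id) {
    if (id < 0) return(-id)
    c(walk(merge[id, 1]), walk(merge[id, 2]))
  }
  walk(nrow(merge))
}

#' @export
print.upgma <- function(x, ...) {
  cat(sprintf("UPGMA tree on %d taxa (%d merges, final height %.6g)\n",
              length(x$tree$tip.label), nrow(x$trace),
              max(x$trace$height)))
  invisible(x)
}

#' Jaccard (binary) gene-content distance matrix
#'
#' `d(i, j) = 1 - |P_i intersect P_j| / |P_i union P_j|` over the presence
#' sets of the two genomes (copy counts are binarized). Shared absences
#' carry no weight, so all-zero clusters do not affect the result. Values
#' lie in [0, 1].
#'
#' @param m a presence/absence count matrix; every genome must possess at
#'   least one cluster.
#' @return a labeled distance matrix over the genomes.
#' @export
jaccard_matrix <- function(m) {
  m <- validate_presence_absence(m)
  x <- m > 0
  empty <- rownames(m)[rowSums(x) == 0]
  if (length(empty))
    ex_stop("jaccard_matrix: genome(s) with empty presence set: ",
            paste(head(empty, 5), collapse = ", "))
  d <- as.matrix(stats::dist(x, method = "binary"))
  validate_dist_matrix(d)
}
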