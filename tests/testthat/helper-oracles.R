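# Independent oracles and fixture builders used across the suite. These
# deliberately re-derive quantities by the most transparent method available
# (path walking, exhaustive enumeration, naive recomputation) and stay
# independent of the package's production code paths.

# random labeled distance matrix (positive off-diagonal, no structure)
rand_dist <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  v <- runif(n * (n - 1) / 2, 0.1, 10)
  d[upper.tri(d)] <- v
  d <- d + t(d)
  d
}

# patristic distances by explicit root-to-leaf path walking
naive_patristic <- function(tree) {
  n <- length(tree$tip.label)
  parent <- rep(NA_integer_, n + tree$Nnode)
  plen <- rep(NA_real_, n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- c(); lens <- c()
    while (!is.na(parent[v])) {
      nodes <- c(nodes, v); lens <- c(lens, plen[v]); v <- parent[v]
    }
    data.frame(node = nodes, len = lens)
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi$node, pj$node)
    d[i, j] <- d[j, i] <- sum(pi$len[!pi$node %in% shared]) +
      sum(pj$len[!pj$node %in% shared])
  }
  d
}

# naive UPGMA reference: cluster averages recomputed from the original
# matrix at every step (same tie-break convention as the implementation)
naive_upgma_trace <- function(d) {
  labs <- rownames(d)
  clusters <- as.list(labs)
  heights <- c(); a <- c(); b <- c()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      cand_min <- min(min(clusters[[i]]), min(clusters[[j]]))
      cand_max <- max(min(clusters[[i]]), min(clusters[[j]]))
      if (avg < best - 1e-12) {
        best <- avg; bi <- i; bj <- j
      } else if (abs(avg - best) <= 1e-12) {
        cur_min <- min(min(clusters[[bi]]), min(clusters[[bj]]))
        cur_max <- max(min(clusters[[bi]]), min(clusters[[bj]]))
        if (cand_min < cur_min ||
            (cand_min == cur_min && cand_max < cur_max)) {
          bi <- i; bj <- j
        }
      }
    }
    a <- c(a, min(clusters[[bi]])); b <- c(b, min(clusters[[bj]]))
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  data.frame(a = pmin(a, b), b = pmax(a, b), height = heights)
}

# exhaustive Fitch oracle: minimum state changes over all internal labelings
exhaustive_min_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  edge <- tree$edge
  leaf_state <- as.integer(states[tree$tip.label])
  best <- Inf
  for (mask in 0:(2^nnode - 1)) {
    lab <- c(leaf_state,
             as.integer(bitwAnd(mask, 2^(seq_len(nnode) - 1)) > 0))
    changes <- sum(lab[edge[, 1]] != lab[edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# --- independent random/unrooted topology machinery (parent pointers) -----

# uniform unrooted binary topology on n leaves by stepwise addition;
# returns parent vector + tip flags (node 1 is the internal "root" of the
# working representation)
rand_pp_topology <- function(n) {
  parent <- c(NA_integer_, 1L, 1L, 1L)
  is_tip <- c(FALSE, TRUE, TRUE, TRUE)
  leaf_no <- c(NA_integer_, 1L, 2L, 3L)
  for (k in seq_len(n - 3) + 3L) {
    edges <- which(!is.na(parent))
    e <- edges[sample.int(length(edges), 1)]
    newint <- length(parent) + 1L
    parent <- c(parent, parent[e], newint)
    is_tip <- c(is_tip, FALSE, TRUE)
    leaf_no <- c(leaf_no, NA_integer_, k)
    parent[e] <- newint
  }
  list(parent = parent, is_tip = is_tip, leaf_no = leaf_no, n = n)
}

# all unrooted binary topologies on n leaves (recursive edge insertion)
all_pp_topologies <- function(n) {
  grow <- function(tp, k) {
    if (k > n) return(list(tp))
    out <- list()
    for (e in which(!is.na(tp$parent))) {
      t2 <- tp
      newint <- length(t2$parent) + 1L
      t2$parent <- c(t2$parent, t2$parent[e], newint)
      t2$is_tip <- c(t2$is_tip, FALSE, TRUE)
      t2$leaf_no <- c(t2$leaf_no, NA_integer_, k)
      t2$parent[e] <- newint
      out <- c(out, grow(t2, k + 1L))
    }
    out
  }
  base <- list(parent = c(NA_integer_, 1L, 1L, 1L),
               is_tip = c(FALSE, TRUE, TRUE, TRUE),
               leaf_no = c(NA_integer_, 1L, 2L, 3L), n = n)
  grow(base, 4L)
}

# canonical split bitmasks (non-trivial) of a parent-pointer topology;
# leaves numbered 1..n, n <= 30
pp_split_masks <- function(tp) {
  n <- tp$n
  full <- bitwShiftL(1L, n) - 1L
  nn <- length(tp$parent)
  mask <- integer(nn)
  dep <- integer(nn)                     # vectorized depth computation
  cur <- tp$parent
  while (any(ok <- !is.na(cur))) {
    dep[ok] <- dep[ok] + 1L
    cur[ok] <- tp$parent[cur[ok]]
  }
  ord <- order(dep, decreasing = TRUE)   # deep nodes first
  for (v in ord) {
    if (tp$is_tip[v]) mask[v] <- bitwShiftL(1L, tp$leaf_no[v] - 1L)
    if (!is.na(tp$parent[v]))
      mask[tp$parent[v]] <- bitwOr(mask[tp$parent[v]], mask[v])
  }
  splits <- integer(0)
  for (v in which(!is.na(tp$parent) & !tp$is_tip)) {
    m <- mask[v]
    sz <- sum(bitwAnd(m, bitwShiftL(1L, 0:(n - 1))) > 0)
    if (sz < 2 || sz > n - 2) next
    comp <- bitwAnd(bitwNot(m), full)
    splits <- c(splits, min(m, comp))
  }
  unique(splits)
}

pp_rf <- function(tp1, tp2) {
  s1 <- pp_split_masks(tp1); s2 <- pp_split_masks(tp2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

# phylo from a parent-pointer topology, unit branch lengths
pp_topology_phylo <- function(tp, labels = sprintf("L%02d", seq_len(tp$n))) {
  kids <- split(seq_along(tp$parent), tp$parent)
  build <- function(v) {
    if (tp$is_tip[v]) return(paste0(labels[tp$leaf_no[v]], ":1"))
    paste0("(", paste(vapply(kids[[as.character(v)]], build, character(1)),
                      collapse = ","), ")",
           if (is.na(tp$parent[v])) "" else ":1")
  }
  ape::read.tree(text = paste0(build(which(is.na(tp$parent))), ";"))
}

# affine-gap Needleman-Wunsch oracle (BLOSUM62, gap open 11, extend 1;
# a gap of length L costs 11 + L). Returns the optimal global score, which
# is unambiguous even when several co-optimal alignments exist.
nw_score_oracle <- function(a, b) {
  S <- blosum62_matrix()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  GO <- 11; GE <- 1
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -GO - GE * i
  for (j in seq_len(m)) Y[1, j + 1] <- -GO - GE * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- S[av[i], bv[j]]
    M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
    X[i + 1, j + 1] <- max(M[i, j + 1] - GO - GE, X[i, j + 1] - GE)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - GO - GE, Y[i + 1, j] - GE)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- get("BLOSUM62", envir = e)
    }
    cache
  }
})

# score of an explicit gapped alignment (two equal-length strings)
score_alignment <- function(p, s) {
  S <- blosum62_matrix()
  pv <- strsplit(p, "")[[1]]; sv <- strsplit(s, "")[[1]]
  score <- 0
  gap_p <- gap_s <- FALSE
  for (k in seq_along(pv)) {
    if (pv[k] == "-") {
      score <- score - (if (gap_p) 1 else 12); gap_p <- TRUE; gap_s <- FALSE
    } else if (sv[k] == "-") {
      score <- score - (if (gap_s) 1 else 12); gap_s <- TRUE; gap_p <- FALSE
    } else {
      score <- score + S[pv[k], sv[k]]; gap_p <- gap_s <- FALSE
    }
  }
  score
}

# small planted scenario used by several files
small_scenario <- function(seed = 7, ...) {
  args <- list(n_taxa = 24, n_species = 4, n_genes = 8,
               transfers_per_gene = 0, gene_rate_sigma = 0,
               ani_noise_sd = 0, af_noise_sd = 0,
               n_aux_clusters = 150, seed = seed)
  do.call(scenario_spec, utils::modifyList(args, list(...)))
}

partition_matches_truth <- function(partition, truth) {
  planted <- lapply(split(truth$genome, truth$species), sort)
  found <- lapply(partition$species, sort)
  setequal(planted, found)
}
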