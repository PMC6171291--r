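# Parent-pointer tree representation used internally by the tree
# simulators: a vector of parent indices (NA at the root), a branch length
# above each node, tip labels (NA for internal nodes), and a tip flag.
# Conversions go through newick, which keeps the code simple and exercises
# the same serialization path users rely on.

pp_to_phylo <- function(parent, len, tip_lab, is_tip, root = NULL) {
  if (is.null(root)) root <- which(is.na(parent))[1]
  kids <- split(seq_along(parent), parent)
  # node depths, vectorized (no recursion: trees can be ~10^3 deep)
  nn <- length(parent)
  dep <- integer(nn)
  cur <- parent
  while (any(ok <- !is.na(cur))) {
    dep[ok] <- dep[ok] + 1L
    cur[ok] <- parent[cur[ok]]
  }
  str <- character(nn)
  str[is_tip] <- tip_lab[is_tip]
  for (v in order(dep, decreasing = TRUE)) {       # deepest first
    if (!is_tip[v] && !is.null(kids[[as.character(v)]]))
      str[v] <- paste0("(", paste(str[kids[[as.character(v)]]],
                                  collapse = ","), ")")
    if (!is.na(parent[v]) && nzchar(str[v]))
      str[v] <- paste0(str[v], ":", sprintf("%.10g", len[v]))
  }
  ape::read.tree(text = paste0(str[root], ";"))
}

phylo_to_pp <- function(tree) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  parent <- rep(NA_integer_, nn)
  len <- rep(NA_real_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  len[tree$edge[, 2]] <- tree$edge.length
  is_tip <- seq_len(nn) <= ntip
  tip_lab <- c(tree$tip.label, rep(NA_character_, tree$Nnode))
  # node ages (height above the tips) for ultrametric trees
  depth <- ape::node.depth.edgelength(tree)
  age <- max(depth) - depth
  list(parent = parent, len = len, tip_lab = tip_lab, is_tip = is_tip,
       age = age)
}
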