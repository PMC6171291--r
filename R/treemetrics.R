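#' Patristic distance matrix of a tree
#'
#' Entry (i, j) is the sum of branch lengths along the path between leaves
#' i and j (the cophenetic distance). Every edge must carry a length.
#'
#' @param tree a `"phylo"` tree with branch lengths.
#' @return a labeled distance matrix over the tip labels.
#' @export
patristic_matrix <- function(tree) {
  validate_tree(tree, lengths = TRUE)
  d <- stats::cophenetic(tree)
  validate_dist_matrix(d, tol = 1e-6)
}

#' Average a list of distance matrices entrywise
#'
#' All matrices must share one label set; each is aligned to the label
#' order of the first before the arithmetic mean is taken. This is the
#' genome-wide relatedness measure: per-gene patristic distances averaged
#' across the core genome.
#'
#' @param matrices a list of labeled distance matrices.
#' @return the entrywise mean, labeled like the first matrix.
#' @export
average_matrices <- function(matrices) {
  if (!length(matrices)) ex_stop("average_matrices: empty list")
  labs <- sort(rownames(matrices[[1]]))
  acc <- NULL
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    if (!setequal(rownames(m), labs)) {
      diff <- c(setdiff(labs, rownames(m)), setdiff(rownames(m), labs))
      ex_stop("average_matrices: matrix ", i, " label mismatch: ",
              paste(head(diff, 5), collapse = ", "))
    }
    m <- m[labs, labs]
    acc <- if (is.null(acc)) m else acc + m
  }
  ord <- rownames(matrices[[1]])
  validate_dist_matrix((acc / length(matrices))[ord, ord], tol = 1e-6)
}

#' Squared Pearson correlation of two distance matrices
#'
#' Computed over the strictly upper-triangular entries after aligning the
#' second matrix to the first's labels.
#'
#' @param a,b labeled distance matrices over the same label set.
#' @return R-squared in [0, 1]; zero variance in either triangle is an
#'   error.
#' @export
matrix_r2 <- function(a, b) {
  labs <- rownames(a)
  if (!setequal(labs, rownames(b)))
    ex_stop("matrix_r2: label sets differ")
  if (length(labs) < 3) ex_stop("matrix_r2: need at least 3 taxa")
  b <- b[labs, labs]
  ut <- upper.tri(a)
  x <- a[ut]; y <- b[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    ex_stop("matrix_r2: zero variance in a triangle; correlation undefined")
  stats::cor(x, y)^2
}

# canonical string keys for the non-trivial splits (bipartitions) of a tree,
# unrooted interpretation; the key names the smaller side (ties: the side
# holding the lexicographically smallest label)
split_keys <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4) return(character(0))
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(idx) {
    k <- length(idx)
    if (k < 2 || k > n - 2) return(NA_character_)
    side <- if (k < n - k) labs[idx]
    else if (k > n - k) labs[-idx]
    else { a <- labs[idx]; b <- labs[-idx]
           if (min(a) < min(b)) a else b }
    paste(sort(side), collapse = "\r")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Non-trivial bipartitions of a tree
#'
#' One bipartition per internal edge under the unrooted interpretation
#' (the two edges at the root of a rooted binary tree induce the same
#' split, which is reported once). Trivial splits -- those cutting off a
#' single leaf or all but one -- are omitted, so a fully resolved tree on
#' n leaves yields n - 3 splits.
#'
#' @param tree a `"phylo"` tree with at least 4 leaves for a nonempty
#'   result.
#' @return a list of character vectors, each the canonical (smaller) side
#'   of one split; the full leaf set is attached as attribute `leaves`.
#' @export
bipartitions <- function(tree) {
  validate_tree(tree)
  keys <- split_keys(tree)
  out <- lapply(strsplit(keys, "\r", fixed = TRUE), identity)
  attr(out, "leaves") <- sort(tree$tip.label)
  out
}

#' Robinson-Foulds distance between two trees
#'
#' The number of non-trivial bipartitions present in exactly one of the two
#' trees (symmetric difference), computed on the unrooted interpretation;
#' rooted inputs are implicitly unrooted. For two fully resolved trees on
#' n leaves the distance lies in `[0, 2(n-3)]` and is even.
#'
#' @param a,b `"phylo"` trees on the same leaf set.
#' @return the RF distance (integer).
#' @export
robinson_foulds <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label))
    ex_stop("robinson_foulds: leaf sets differ")
  ka <- split_keys(a)
  kb <- split_keys(b)
  length(setdiff(ka, kb)) + length(setdiff(kb, ka))
}

#' Concordance factor of a clade across gene trees
#'
#' The fraction of gene trees containing the bipartition
#' `group | complement` (unrooted containment).
#'
#' @param group a leaf-label set; must be non-trivial (2 to n-2 labels).
#' @param gene_trees a list of `"phylo"` trees sharing a leaf set that
#'   includes `group`.
#' @return a fraction in [0, 1].
#' @export
concordance_factor <- function(group, gene_trees) {
  if (!length(gene_trees)) ex_stop("concordance_factor: no trees")
  labs <- sort(gene_trees[[1]]$tip.label)
  if (!all(group %in% labs))
    ex_stop("concordance_factor: group labels missing from the trees")
  n <- length(labs)
  k <- length(unique(group))
  if (k < 2 || k > n - 2)
    ex_stop("concordance_factor: trivial split (group size ", k,
            " of ", n, ")")
  side <- if (k < n - k) sort(unique(group))
  else if (k > n - k) sort(setdiff(labs, group))
  else { a <- sort(unique(group)); b <- sort(setdiff(labs, group))
         if (min(a) < min(b)) a else b }
  key <- paste(side, collapse = "\r")
  mean(vapply(gene_trees, function(t) key %in% split_keys(t), logical(1)))
}

# --- Fitch parsimony -------------------------------------------------------

# Vectorized bottom-up/top-down Fitch engine over many binary characters.
# X: leaves x characters 0/1 matrix (rownames = tip labels).
# Generalizes to multifurcations by the frequency rule (a state enters a
# node's set when it occurs in the maximal number of child sets; the added
# change count is #children minus that maximum), which reduces to the
# classic intersection/union rule on bifurcations and preserves the global
# parsimony minimum for two states.
fitch_engine <- function(tree, X, root_state = 0L) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- ntip + nnode
  nchar_ <- ncol(X)
  X <- X[tree$tip.label, , drop = FALSE]
  S0 <- matrix(FALSE, total, nchar_)
  S1 <- matrix(FALSE, total, nchar_)
  S0[seq_len(ntip), ] <- X == 0
  S1[seq_len(ntip), ] <- X == 1
  edge <- tree$edge
  children <- split(edge[, 2], edge[, 1])
  # postorder over internal nodes (children always precede their parent)
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  for (nd in po) {
    ch <- children[[as.character(nd)]]
    k0 <- colSums(S0[ch, , drop = FALSE])
    k1 <- colSums(S1[ch, , drop = FALSE])
    K <- pmax(k0, k1)
    S0[nd, ] <- k0 == K
    S1[nd, ] <- k1 == K
  }
  root <- po[length(po)]
  state <- matrix(NA_integer_, total, nchar_)
  state[root, ] <- ifelse(S0[root, ] & S1[root, ], root_state,
                          ifelse(S1[root, ], 1L, 0L))
  # preorder resolution: keep the parent's state when the node's set allows
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  for (i in seq_len(nrow(pre))) {
    par <- pre[i, 1]; ch <- pre[i, 2]
    ps <- state[par, ]
    keep0 <- ps == 0L & S0[ch, ]
    keep1 <- ps == 1L & S1[ch, ]
    state[ch, ] <- ifelse(keep0, 0L, ifelse(keep1, 1L,
                                            ifelse(S1[ch, ], 1L, 0L)))
  }
  pstate <- state[pre[, 1], , drop = FALSE]
  cstate <- state[pre[, 2], , drop = FALSE]
  gain_mat <- pstate == 0L & cstate == 1L
  loss_mat <- pstate == 1L & cstate == 0L
  list(
    gains = sum(gain_mat), losses = sum(loss_mat),
    per_branch_gains = rowSums(gain_mat),
    per_branch_losses = rowSums(loss_mat),
    branch_child = pre[, 2],
    per_char_changes = colSums(gain_mat) + colSums(loss_mat)
  )
}

#' Parsimony gains and losses of a binary character on a rooted tree
#'
#' Bottom-up Fitch state sets followed by a top-down pass that keeps the
#' parental state wherever the node's set permits, so ambiguity is resolved
#' from the root downward. A root whose set is ambiguous is resolved to
#' `root_state` (absent by default: auxiliary genes missing from the core
#' are treated as ancestrally absent). Transitions 0 to 1 are gains, 1 to 0
#' losses; their total is the Fitch parsimony minimum.
#'
#' @param tree a rooted `"phylo"` tree.
#' @param character named 0/1 vector over the tip labels.
#' @param root_state state used when the root's Fitch set is ambiguous.
#' @return an object of class `"gain_loss"`: a list with `total`, `gains`,
#'   `losses`, `branch_count`, and `per_branch` (data.frame: child node,
#'   gains, losses).
#' @export
fitch_gains_losses <- function(tree, character, root_state = 0L) {
  missing <- setdiff(tree$tip.label, names(character))
  if (length(missing))
    ex_stop("fitch_gains_losses: no state for leaf ", missing[1])
  if (!all(character %in% c(0, 1)))
    ex_stop("fitch_gains_losses: states must be 0/1")
  X <- matrix(as.integer(character[tree$tip.label]), ncol = 1,
              dimnames = list(tree$tip.label, "char"))
  res <- fitch_engine(tree, X, root_state = as.integer(root_state))
  structure(list(
    total = res$gains + res$losses,
    gains = res$gains, losses = res$losses,
    branch_count = nrow(tree$edge),
    per_branch = data.frame(child = res$branch_child,
                            gains = res$per_branch_gains,
                            losses = res$per_branch_losses)
  ), class = "gain_loss")
}

#' @export
print.gain_loss <- function(x, ...) {
  cat("Parsimony gain/loss summary\n")
  cat(sprintf("  total changes : %d (%d gains, %d losses)\n",
              x$total, x$gains, x$losses))
  cat(sprintf("  branches      : %d\n", x$branch_count))
  if (!is.null(x$per_branch_average))
    cat(sprintf("  per-branch    : %.1f gains, %.1f losses\n",
                x$per_branch_average["gains"],
                x$per_branch_average["losses"]))
  invisible(x)
}

#' Map pan-genome gene content onto a tree by Fitch parsimony
#'
#' Sums gains and losses over all clusters present in at least two genomes
#' (all-present core clusters contribute no changes and are skipped).
#' Per-branch averages divide the totals by the number of branches of the
#' unrooted tree, `2n - 3` for a fully resolved tree on n leaves.
#'
#' @param tree a rooted `"phylo"` tree whose tips are the genomes.
#' @param m a presence/absence count matrix over the same genomes.
#' @param root_state see [fitch_gains_losses()].
#' @return a `"gain_loss"` object with additional fields
#'   `per_branch_average` and `clusters_used`.
#' @export
map_pan_genome <- function(tree, m, root_state = 0L) {
  m <- validate_presence_absence(m)
  if (!setequal(tree$tip.label, rownames(m)))
    ex_stop("map_pan_genome: tree leaves and matrix genomes differ")
  X <- (m > 0) * 1L
  npres <- colSums(X)
  use <- npres >= 2 & npres < nrow(X)   # variable pan clusters only
  branch_count <- nrow(ape::unroot(tree)$edge)
  if (!any(use)) {
    res <- list(gains = 0L, losses = 0L,
                per_branch_gains = numeric(0), per_branch_losses = numeric(0),
                branch_child = integer(0))
  } else {
    res <- fitch_engine(tree, X[, use, drop = FALSE],
                        root_state = as.integer(root_state))
  }
  structure(list(
    total = res$gains + res$losses,
    gains = res$gains, losses = res$losses,
    branch_count = branch_count,
    per_branch_average = c(gains = res$gains / branch_count,
                           losses = res$losses / branch_count),
    clusters_used = sum(use),
    per_branch = if (length(res$branch_child))
      data.frame(child = res$branch_child,
                 gains = res$per_branch_gains,
                 losses = res$per_branch_losses)
    else data.frame(child = integer(0), gains = integer(0),
                    losses = integer(0))
  ), class = "gain_loss")
}
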