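# Null distribution of the Robinson-Foulds distance between two
# independent uniformly random fully resolved unrooted trees.
#
# The number of possible splits with side sizes (a, n-a) is C(n, a)
# (halved when a = n/2), and a uniformly random tree contains a given
# such split with probability
#   p_a = (2a-3)!! (2(n-a)-3)!! / (2n-5)!!,
# since an unrooted binary tree containing the split decomposes into two
# rooted binary trees joined at the split edge. By independence the
# expected number of splits shared by two random trees is
#   E[S] = sum_a c_a p_a^2 ,
# exactly; the RF distance is then 2(n-3) - 2 S. The tail of S is well
# approximated by a Poisson law with mean E[S] (E[S] tends to 1/8 as n
# grows), which is what the log-tail function uses; all tail arithmetic is
# carried in log10 space because the probabilities of interest lie far
# below double-precision underflow.

# log of the double factorial (2k-3)!!, with (-1)!! = 1!! = 1
ldf <- function(k) lfactorial(2 * k - 2) - (k - 1) * log(2) - lfactorial(k - 1)

# (2n-5)!! = ldf(n-1) is the number of unrooted binary trees on n leaves
log_split_prob <- function(a, n) ldf(a) + ldf(n - a) - ldf(n - 1)

#' Null distribution of RF distances for random trees
#'
#' Expected Robinson-Foulds distance between two independent uniformly
#' random fully resolved unrooted trees on `n` leaves, together with a
#' log10 tail-probability function for observing an RF distance at most a
#' given value. The expectation is exact; tail probabilities use a Poisson
#' approximation to the shared-split count (whose mean tends to 1/8), with
#' all sums carried in log space.
#'
#' @param n leaf count, at least 4.
#' @return an object of class `"rf_null"`: a list with `n`,
#'   `expected_shared` (expected number of shared non-trivial splits),
#'   `expected_rf`, `max_rf` = `2(n-3)`, and `log10_tail`, a function
#'   mapping an RF value `x` to `log10 P(RF <= x)`.
#' @export
#' @examples
#' null <- random_rf_null(4)
#' null$expected_rf  # 4/3: two random quartets agree with probability 1/3
random_rf_null <- function(n) {
  if (!is_count(n) || n < 4) ex_stop("random_rf_null: need n >= 4")
  n <- as.integer(n)
  amax <- n %/% 2
  a <- 2:amax
  lc <- lchoose(n, a) - ifelse(a == n - a, log(2), 0)
  terms <- exp(lc + 2 * log_split_prob(a, n))
  lambda <- sum(terms)
  max_rf <- 2 * (n - 3)
  log10_tail <- function(x) {
    # P(RF <= x) = P(S >= (max_rf - x) / 2) under the Poisson approximation
    vapply(x, function(xi) {
      s0 <- ceiling((max_rf - xi) / 2)
      if (s0 <= 0) return(0)
      k <- s0:(s0 + 300L)
      lp <- -lambda + k * log(lambda) - lfactorial(k)
      m <- max(lp)
      (m + log(sum(exp(lp - m)))) / log(10)
    }, numeric(1))
  }
  structure(list(n = n, expected_shared = lambda,
                 expected_rf = max_rf - 2 * lambda,
                 max_rf = max_rf, log10_tail = log10_tail),
            class = "rf_null")
}

#' @export
print.rf_null <- function(x, ...) {
  cat(sprintf(
    "RF null for uniformly random unrooted binary trees (n = %d)\n", x$n))
  cat(sprintf("  max RF            : %d\n", x$max_rf))
  cat(sprintf("  expected shared   : %.6g splits\n", x$expected_shared))
  cat(sprintf("  expected RF       : %.6g\n", x$expected_rf))
  invisible(x)
}

#' Uniformly random unrooted binary tree topology
#'
#' Grown by stepwise random addition: leaf k+1 is attached to an edge
#' chosen uniformly among the current `2k - 5` edges (counting the root
#' "edge" of the working rooted representation appropriately), which makes
#' every unrooted fully resolved topology on the label set equally likely.
#' Branch lengths are all 1.
#'
#' @param labels tip labels (length at least 4), or an integer `n` to use
#'   labels `t1..tn`.
#' @return an unrooted `"phylo"` tree.
#' @export
random_topology <- function(labels) {
  if (length(labels) == 1 && is.numeric(labels))
    labels <- sprintf("t%d", seq_len(labels))
  n <- length(labels)
  if (n < 4) ex_stop("random_topology: need at least 4 labels")
  # parent-pointer representation; start from the 3-leaf star
  parent <- c(NA_integer_, 1L, 1L, 1L)   # node 1 = center
  is_tip <- c(FALSE, TRUE, TRUE, TRUE)
  tip_lab <- c(NA, labels[1:3])
  for (k in 4:n) {
    edges <- which(!is.na(parent))       # edge above each non-root node
    e <- edges[sample.int(length(edges), 1)]
    newint <- length(parent) + 1L
    newtip <- length(parent) + 2L
    parent <- c(parent, parent[e], newint)
    is_tip <- c(is_tip, FALSE, TRUE)
    tip_lab <- c(tip_lab, NA, labels[k])
    parent[e] <- newint
  }
  pp_to_phylo(parent, rep(1, length(parent)), tip_lab, is_tip)
}
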