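#' Does a genome pair meet the joint ANI/AF threshold?
#'
#' True iff the pair's ANI is at least `cfg$ani_min` and its AF at least
#' `cfg$af_min` (both boundaries inclusive). A pair absent from the table
#' fails the criterion, with a warning: splitting is the conservative
#' outcome.
#'
#' @param a,b genome labels.
#' @param pairs a symmetrized pair-similarity table
#'   (see [read_pair_similarity()]).
#' @param cfg an [analysis_config()].
#' @return logical.
#' @export
pair_meets_threshold <- function(a, b, pairs, cfg = analysis_config()) {
  ga <- pmin(a, b); gb <- pmax(a, b)
  i <- match(paste(ga, gb), paste(pairs$genome_a, pairs$genome_b))
  if (is.na(i)) {
    ex_warn("pair_meets_threshold: pair ", ga, " / ", gb,
            " absent from the similarity table; treating as failing")
    return(FALSE)
  }
  pairs$ani[i] >= cfg$ani_min && pairs$af[i] >= cfg$af_min
}

# linkage test for a candidate group on precomputed lookup matrices
group_meets_linkage <- function(group, ok, linkage) {
  sub <- ok[group, group, drop = FALSE]
  diag(sub) <- NA
  switch(linkage,
    complete = all(sub[upper.tri(sub)]),
    single = {
      g <- igraph::graph_from_adjacency_matrix(
        (!is.na(sub)) & sub, mode = "undirected", diag = FALSE)
      igraph::components(g)$no == 1
    },
    single_literal = all(apply(sub, 1, any, na.rm = TRUE))
  )
}

#' Delimit species as the largest exclusive ANI/AF-compatible groups
#'
#' Builds the UPGMA tree of the relatedness matrix `d`, scores every clade
#' for exclusivity, and walks the tree from the root: each genome is
#' assigned to the most inclusive clade that (a) is exclusive at the
#' configured slack (`score > -cfg$exclusivity_slack`) and (b) satisfies
#' the linkage criterion on the ANI/AF table -- complete-linkage: every
#' within-group pair meets the joint threshold; single-linkage: the
#' members form one connected single-linkage cluster of the threshold
#' graph, so each meets the threshold with at least one other member and
#' no block of the group is isolated from the rest. Once a clade qualifies
#' its descendants are not revisited, and the nestedness of clades makes
#' the result a partition; genomes claimed by no qualifying clade become
#' singleton species (trivially exclusive).
#'
#' @param d a labeled relatedness (distance) matrix over the genomes.
#' @param pairs a symmetrized ANI/AF pair table.
#' @param cfg an [analysis_config()]; `linkage`, `ani_min`, `af_min` and
#'   `exclusivity_slack` are used.
#' @return a list of class `"species_partition"`: `species` (list of
#'   label vectors, largest first), `provenance` (per species: the UPGMA
#'   node id or `"singleton"`), `table` (data.frame `genome`, `species`,
#'   `size`, `provenance`), plus the thresholds used.
#' @export
delimit_species <- function(d, pairs, cfg = analysis_config()) {
  d <- validate_dist_matrix(d)
  genomes <- rownames(d)
  lk <- pair_lookup(pairs, genomes)
  ok <- !is.na(lk$ani) & !is.na(lk$af) &
    lk$ani >= cfg$ani_min & lk$af >= cfg$af_min
  up <- upgma(d)
  tree <- up$tree
  ntip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  recs <- score_tree_clades(tree, d)
  qualifies <- logical(ntip + tree$Nnode)
  for (i in seq_len(nrow(recs))) {
    grp <- strsplit(recs$members[i], ";", fixed = TRUE)[[1]]
    if (recs$score[i] > -cfg$exclusivity_slack &&
        group_meets_linkage(grp, ok, cfg$linkage))
      qualifies[recs$node[i]] <- TRUE
  }
  # root-down sweep: first qualifying clade on each root-to-tip path wins
  species <- list()
  provenance <- character(0)
  assigned <- character(0)
  pre <- ape::reorder.phylo(tree, "cladewise")$edge
  visit <- c((ntip + 1L), pre[, 2])     # root first, then preorder children
  blocked <- logical(ntip + tree$Nnode)
  parent_of <- rep(NA_integer_, ntip + tree$Nnode)
  parent_of[pre[, 2]] <- pre[, 1]
  for (nd in visit) {
    p <- parent_of[nd]
    if (!is.na(p) && blocked[p]) { blocked[nd] <- TRUE; next }
    if (nd > ntip && qualifies[nd]) {
      grp <- sort(labs[pp[[nd - ntip]]])
      species[[length(species) + 1L]] <- grp
      provenance <- c(provenance, sprintf("clade_%d", nd))
      assigned <- c(assigned, grp)
      blocked[nd] <- TRUE
    }
  }
  for (g in sort(setdiff(genomes, assigned))) {
    species[[length(species) + 1L]] <- g
    provenance <- c(provenance, "singleton")
  }
  ord <- order(-lengths(species),
               vapply(species, function(s) s[1], character(1)))
  species <- species[ord]
  provenance <- provenance[ord]
  tab <- do.call(rbind, lapply(seq_along(species), function(i)
    data.frame(genome = species[[i]], species = sprintf("SP%04d", i),
               size = length(species[[i]]), provenance = provenance[i],
               stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  structure(list(species = species, provenance = provenance, table = tab,
                 linkage = cfg$linkage, ani_min = cfg$ani_min,
                 af_min = cfg$af_min, slack = cfg$exclusivity_slack,
                 upgma = up),
            class = "species_partition")
}

#' @export
print.species_partition <- function(x, ...) {
  s <- summarize_partition(x)
  cat(sprintf(
    "Species partition (%s linkage, ANI >= %.1f%%, AF >= %.2f, slack %g)\n",
    x$linkage, x$ani_min, x$af_min, x$slack))
  cat(sprintf(
    "  %d species over %d genomes: %d singletons, largest %d, mean size %.2f\n",
    s$n_species, s$n_genomes, s$n_singletons, s$largest, s$mean_size))
  invisible(x)
}

#' Conspecific-split report
#'
#' Among the genome pairs that meet the joint ANI/AF threshold, counts how
#' many were placed into different species by the exclusivity criterion.
#' A low ratio means exclusivity does not over-split conventional species.
#'
#' @param partition a [delimit_species()] result.
#' @param pairs a symmetrized ANI/AF table.
#' @param cfg an [analysis_config()].
#' @return a list of class `"split_report"`: `n_meeting`, `n_split`,
#'   `ratio` (0 when no pair meets the threshold).
#' @export
split_report <- function(partition, pairs, cfg = analysis_config()) {
  genomes <- unlist(partition$species)
  meets <- pairs$ani >= cfg$ani_min & pairs$af >= cfg$af_min &
    pairs$genome_a %in% genomes & pairs$genome_b %in% genomes
  mp <- pairs[meets, , drop = FALSE]
  sp <- setNames(partition$table$species, partition$table$genome)
  n_split <- sum(sp[mp$genome_a] != sp[mp$genome_b])
  structure(list(
    n_meeting = nrow(mp), n_split = n_split,
    ratio = if (nrow(mp)) n_split / nrow(mp) else 0
  ), class = "split_report")
}

#' @export
print.split_report <- function(x, ...) {
  cat(sprintf(
    "Conspecific splits: %d of %d threshold-meeting pairs (%.1f%%) in different species\n",
    x$n_split, x$n_meeting, 100 * x$ratio))
  invisible(x)
}

#' Summary statistics of a species partition
#'
#' @param partition a [delimit_species()] result.
#' @return a list: `n_species`, `n_genomes`, `n_singletons`, `largest`,
#'   `mean_size`.
#' @export
summarize_partition <- function(partition) {
  sz <- lengths(partition$species)
  list(n_species = length(sz), n_genomes = sum(sz),
       n_singletons = sum(sz == 1L), largest = max(sz),
       mean_size = mean(sz))
}
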