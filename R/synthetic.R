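#' Scenario specification for the synthetic benchmark generator
#'
#' Defines a planted-species scenario: a clock-like species tree with
#' `n_species` shallow clades separated from the deeper backbone, gene
#' trees made discordant by horizontal transfers, auxiliary gene content
#' evolving by gain and loss, and ANI/AF decreasing monotonically in
#' genome distance.
#'
#' Depth units are arbitrary time: the species tree has total depth 1, so
#' within-species patristic distances are at most `2 * within_depth` and
#' between-species distances at least `2 * depth_sep`. The default
#' `transfers_per_gene` is calibrated so that patristic distance matrices
#' of different genes correlate at a mean R-squared near 0.44, the level
#' observed for real core genes.
#'
#' @param n_taxa number of genomes (>= 4).
#' @param n_species number of planted species clades (>= 2).
#' @param within_depth depth of each within-species subtree.
#' @param depth_sep minimum height of any backbone (between-species) node.
#' @param n_genes number of core genes (gene trees).
#' @param transfers_per_gene Poisson mean of transfer (SPR) events per
#'   gene tree.
#' @param gene_rate_sigma lognormal sigma of the per-gene rate multiplier.
#' @param n_aux_clusters auxiliary (pan-genome) gene clusters to simulate.
#' @param n_core_clusters all-present clusters emitted alongside.
#' @param gain_rate,loss_rate per-unit-time rates of the two-state
#'   presence/absence Markov process below a cluster's origin.
#' @param ani_scale,ani_noise_sd ANI mapping `100 * exp(-ani_scale * d)`
#'   plus Gaussian noise, clamped to [0, 100].
#' @param af_scale,af_max,af_noise_sd AF mapping
#'   `af_max * exp(-af_scale * d)` plus noise, clamped to [0, 1].
#' @param seed RNG seed recorded in every output.
#' @return a list of class `"scenario_spec"`.
#' @export
scenario_spec <- function(n_taxa = 60, n_species = 10,
                          within_depth = 0.05, depth_sep = 0.3,
                          n_genes = 30, transfers_per_gene = 4,
                          gene_rate_sigma = 0.25,
                          n_aux_clusters = 300, n_core_clusters = 30,
                          gain_rate = 0.2, loss_rate = 0.7,
                          ani_scale = 0.3, ani_noise_sd = 0.2,
                          af_scale = 0.5, af_max = 1, af_noise_sd = 0.02,
                          seed = 1) {
  stopifnot(n_taxa >= 4, n_species >= 2, n_species <= n_taxa,
            within_depth > 0, depth_sep > within_depth, depth_sep < 1,
            n_genes >= 1, transfers_per_gene >= 0, gene_rate_sigma >= 0,
            n_aux_clusters >= 0, n_core_clusters >= 0,
            gain_rate >= 0, loss_rate >= 0,
            ani_scale >= 0, ani_noise_sd >= 0,
            af_scale >= 0, af_max > 0, af_max <= 1, af_noise_sd >= 0)
  structure(as.list(environment()), class = "scenario_spec")
}

#' Simulate the clock-like species tree with planted species
#'
#' A coalescent backbone over `n_species` lineages is rescaled so that all
#' between-species divergences are older than `depth_sep`, every pendant
#' backbone edge is extended to total depth 1, and each backbone tip is
#' replaced by an ultrametric within-species subtree of depth
#' `within_depth`. Genomes are labeled `g001 ...` and the planted species
#' assignment is attached as attribute `species` (named character vector).
#'
#' @param spec a [scenario_spec()].
#' @return an ultrametric rooted `"phylo"` tree with attribute `species`.
#' @export
simulate_species_tree <- function(spec) {
  with_seed(spec$seed, {
    k <- spec$n_species
    sizes <- rep(spec$n_taxa %/% k, k)
    extra <- spec$n_taxa %% k
    if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    bb <- ape::rcoal(k, tip.label = sprintf("sp%02d", seq_len(k)))
    depth <- max(ape::node.depth.edgelength(bb))
    bb$edge.length <- bb$edge.length * (1 - spec$depth_sep) / depth
    pend <- match(seq_len(k), bb$edge[, 2])
    bb$edge.length[pend] <- bb$edge.length[pend] + spec$depth_sep
    genome_id <- 0L
    species <- character(0)
    tree <- bb
    for (s in seq_len(k)) {
      lab <- sprintf("sp%02d", s)
      ids <- sprintf("g%03d", genome_id + seq_len(sizes[s]))
      genome_id <- genome_id + sizes[s]
      species[ids] <- lab
      if (sizes[s] == 1L) {
        tree$tip.label[tree$tip.label == lab] <- ids
        next
      }
      sub <- if (sizes[s] == 2L)
        read_newick(sprintf("(%s:%.10g,%s:%.10g);", ids[1],
                            spec$within_depth, ids[2], spec$within_depth))
      else {
        st <- ape::rcoal(sizes[s], tip.label = ids)
        st$edge.length <- st$edge.length * spec$within_depth /
          max(ape::node.depth.edgelength(st))
        st
      }
      where <- which(tree$tip.label == lab)
      tree <- ape::bind.tree(tree, sub, where = where,
                             position = spec$within_depth)
      tree <- ape::drop.tip(tree, lab)
    }
    attr(tree, "species") <- species
    tree
  })
}

# one horizontal-transfer (time-consistent SPR) move on a parent-pointer
# ultrametric tree: at a uniform time, a uniformly chosen living lineage is
# pruned and regrafted onto a uniformly chosen contemporaneous donor edge
hgt_move <- function(pp) {
  t <- runif(1, 0, max(pp$age, na.rm = TRUE) * 0.999)
  alive <- which(!is.na(pp$parent) &
                   pp$age < t & pp$age[pp$parent] > t)
  if (length(alive) < 2) return(pp)
  rec <- alive[sample.int(length(alive), 1)]
  # exclude donors inside the pruned subtree (they move with it)
  in_sub <- function(v) {
    while (!is.na(v)) { if (v == rec) return(TRUE); v <- pp$parent[v] }
    FALSE
  }
  donors <- alive[alive != rec & !vapply(alive, in_sub, logical(1))]
  if (!length(donors)) return(pp)
  don <- donors[sample.int(length(donors), 1)]
  pr <- pp$parent[rec]
  # new node X at age t on the donor edge
  x <- length(pp$parent) + 1L
  pp$parent[x] <- pp$parent[don]
  pp$age[x] <- t
  pp$is_tip[x] <- FALSE
  pp$tip_lab[x] <- NA_character_
  pp$parent[don] <- x
  pp$parent[rec] <- x
  # suppress the old attachment node, now of out-degree 1
  child <- which(!is.na(pp$parent) & pp$parent == pr)
  if (length(child) == 1L) {
    pp$parent[child] <- pp$parent[pr]
    pp$parent[pr] <- NA_integer_
    pp$age[pr] <- NA_real_        # orphaned; dropped at rebuild
    pp$dead <- c(pp$dead %||% integer(0), pr)
  }
  pp
}

pp_rebuild_phylo <- function(pp) {
  keep <- !(seq_along(pp$parent) %in% (pp$dead %||% integer(0)))
  root <- which(is.na(pp$parent) & keep)
  len <- ifelse(is.na(pp$parent), NA_real_, pp$age[pp$parent] - pp$age)
  pp_to_phylo(pp$parent, len, pp$tip_lab, pp$is_tip, root = root)
}

#' Simulate transfer-discordant gene trees
#'
#' Each gene tree starts as a copy of the species tree; a Poisson number of
#' horizontal transfers is applied, each pruning a lineage alive at a
#' uniformly drawn time and regrafting it onto a contemporaneous donor
#' edge (so gene trees stay clock-like); finally all branch lengths are
#' multiplied by a lognormal per-gene rate factor with unit mean.
#'
#' @param species_tree an ultrametric rooted `"phylo"`.
#' @param spec a [scenario_spec()].
#' @return a list of `n_genes` `"phylo"` trees.
#' @export
simulate_gene_trees <- function(species_tree, spec) {
  with_seed(spec$seed + 1L, {
    lapply(seq_len(spec$n_genes), function(g) {
      pp <- phylo_to_pp(species_tree)
      pp$dead <- integer(0)
      for (mv in seq_len(rpois(1, spec$transfers_per_gene)))
        pp <- hgt_move(pp)
      tr <- pp_rebuild_phylo(pp)
      rate <- if (spec$gene_rate_sigma > 0)
        rlnorm(1, -spec$gene_rate_sigma^2 / 2, spec$gene_rate_sigma)
      else 1
      tr$edge.length <- tr$edge.length * rate
      tr
    })
  })
}

# two-state CTMC transition: P(state at the far end | state now) over time t
pa_transition <- function(state, t, gain, loss) {
  tot <- gain + loss
  if (tot == 0) return(state)
  e <- exp(-tot * t)
  p1 <- if (state == 1L) (gain + loss * e) / tot else gain * (1 - e) / tot
  as.integer(runif(1) < p1)
}

#' Simulate presence/absence gene content on a tree
#'
#' Each auxiliary cluster originates at a point drawn uniformly along the
#' tree's total branch length (edges are chosen with probability
#' proportional to their length) and then evolves below that point by a
#' two-state gain/loss Markov process; leaves outside the origin's subtree
#' never carry the cluster. Clusters lost from every leaf are discarded.
#' Core clusters are emitted as all-present columns.
#'
#' @param species_tree a rooted `"phylo"` with branch lengths.
#' @param spec a [scenario_spec()].
#' @return an integer presence/absence matrix (genomes x clusters) whose
#'   auxiliary columns are named `AUX...` and core columns `CORE...`.
#' @export
simulate_presence_absence <- function(species_tree, spec) {
  with_seed(spec$seed + 2L, {
    tree <- species_tree
    ntip <- length(tree$tip.label)
    edge <- tree$edge
    elen <- tree$edge.length
    children <- split(seq_len(nrow(edge)), edge[, 1])  # edge rows per parent
    sim_cluster <- function() {
      e0 <- sample.int(nrow(edge), 1, prob = elen)
      rem0 <- runif(1, 0, elen[e0])    # length from origin down to child
      states <- integer(ntip)
      descend <- function(erow, state, t) {
        s <- pa_transition(state, t, spec$gain_rate, spec$loss_rate)
        child <- edge[erow, 2]
        if (child <= ntip) {
          states[child] <<- s
        } else {
          for (er in children[[as.character(child)]])
            descend(er, s, elen[er])
        }
      }
      descend(e0, 1L, rem0)
      states
    }
    aux <- if (spec$n_aux_clusters > 0)
      vapply(seq_len(spec$n_aux_clusters), function(i) sim_cluster(),
             integer(ntip))
    else matrix(integer(0), ntip, 0)
    keep <- colSums(aux) > 0
    aux <- aux[, keep, drop = FALSE]
    colnames(aux) <- sprintf("AUX%04d", which(keep))
    core <- matrix(1L, ntip, spec$n_core_clusters,
                   dimnames = list(NULL,
                                   sprintf("CORE%03d",
                                           seq_len(spec$n_core_clusters))))
    m <- cbind(core, aux)
    rownames(m) <- tree$tip.label
    validate_presence_absence(m[order(rownames(m)), , drop = FALSE])
  })
}

#' Simulate an ANI/AF table from a distance matrix
#'
#' ANI is `100 * exp(-ani_scale * d)` plus Gaussian noise, clamped to
#' [0, 100]; AF is `af_max * exp(-af_scale * d)` plus noise, clamped to
#' [0, 1]. With zero noise both maps are strictly decreasing in distance.
#'
#' @param d a labeled distance matrix.
#' @param spec a [scenario_spec()].
#' @return a symmetrized pair table (`genome_a`, `genome_b`, `ani`, `af`).
#' @export
simulate_pair_similarity <- function(d, spec) {
  with_seed(spec$seed + 3L, {
    labs <- rownames(d)
    idx <- which(upper.tri(d), arr.ind = TRUE)
    idx <- idx[order(labs[idx[, 1]], labs[idx[, 2]]), , drop = FALSE]
    dv <- d[idx]
    ani <- 100 * exp(-spec$ani_scale * dv)
    af <- spec$af_max * exp(-spec$af_scale * dv)
    if (spec$ani_noise_sd > 0)
      ani <- ani + rnorm(length(ani), 0, spec$ani_noise_sd)
    if (spec$af_noise_sd > 0)
      af <- af + rnorm(length(af), 0, spec$af_noise_sd)
    out <- data.frame(
      genome_a = pmin(labs[idx[, 1]], labs[idx[, 2]]),
      genome_b = pmax(labs[idx[, 1]], labs[idx[, 2]]),
      ani = pmin(pmax(ani, 0), 100),
      af = pmin(pmax(af, 0), spec$af_max),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$genome_a, out$genome_b), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a full benchmark scenario
#'
#' Runs the four generators in sequence and, optionally, writes the
#' standard file layout: `genetrees/gene_NNN.nwk`, `pa.tsv`, `pairs.tsv`,
#' `truth.tsv` (the planted species), `avg_patristic.tsv` and
#' `manifest.json` (seed and parameters).
#'
#' @param spec a [scenario_spec()].
#' @param out_dir optional output directory.
#' @return a list: `spec`, `species_tree`, `gene_trees`, `avg_matrix` (the
#'   averaged per-gene patristic distances), `pa`, `pairs`, `truth`
#'   (data.frame genome/species).
#' @export
simulate_scenario <- function(spec = scenario_spec(), out_dir = NULL) {
  st <- simulate_species_tree(spec)
  gt <- simulate_gene_trees(st, spec)
  avg <- average_matrices(lapply(gt, patristic_matrix))
  pa <- simulate_presence_absence(st, spec)
  pairs <- simulate_pair_similarity(patristic_matrix(st), spec)
  truth <- data.frame(genome = names(attr(st, "species")),
                      species = unname(attr(st, "species")),
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$genome), ]
  rownames(truth) <- NULL
  res <- list(spec = spec, species_tree = st, gene_trees = gt,
              avg_matrix = avg, pa = pa, pairs = pairs, truth = truth)
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "genetrees"), recursive = TRUE,
               showWarnings = FALSE)
    write_newick(st, file.path(out_dir, "species_tree.nwk"))
    for (i in seq_along(gt))
      write_newick(gt[[i]],
                   file.path(out_dir, "genetrees",
                             sprintf("gene_%03d.nwk", i)))
    write_distance_matrix(avg, file.path(out_dir, "avg_patristic.tsv"))
    write_presence_absence(pa, file.path(out_dir, "pa.tsv"))
    write_pair_similarity(pairs, file.path(out_dir, "pairs.tsv"))
    write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- c(list(generator = "exclutax::simulate_scenario"),
                  unclass(spec))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
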