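#' HSSP distance of a local alignment
#'
#' Percent identity above the length-dependent homology threshold curve
#' used to screen low-quality local alignments:
#' `pid - 480 * L^(-0.32 * (1 + exp(-L / 1000)))` for `11 < L <= 450` and
#' `pid - 19.5` for `L > 450`. Alignments of 11 residues or fewer are below
#' the curve's domain and are treated as failing.
#'
#' @param pident percent identity in [0, 100].
#' @param length alignment (match) length in residues; must exceed 11.
#' @return the HSSP distance (vectorized over inputs).
#' @export
#' @examples
#' hssp_distance(100, 500) # 80.5
hssp_distance <- function(pident, length) {
  if (any(pident < 0 | pident > 100))
    ex_stop("hssp_distance: percent identity outside [0, 100]")
  if (any(length <= 11))
    ex_stop("hssp_distance: alignment length must exceed 11 residues")
  thr <- ifelse(length > 450, 19.5,
                480 * length^(-0.32 * (1 + exp(-length / 1000))))
  pident - thr
}

#' Global percent identity of two protein sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with BLOSUM62, gap opening 11 and
#' gap extension 1; identity is the number of identical aligned columns
#' divided by the total number of alignment columns (gap columns included).
#'
#' @param seq_a,seq_b amino-acid sequences (single strings).
#' @return percent identity in [0, 100].
#' @export
#' @examples
#' global_identity("AAAA", "AATA") # 75
global_identity <- function(seq_a, seq_b) {
  if (!nzchar(seq_a) || !nzchar(seq_b))
    ex_stop("global_identity: empty sequence")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  100 * sum(p == s & p != "-") / length(p)
}

#' Filter a hit table by E-value, HSSP distance and match-length fraction
#'
#' Retains hits with E-value at most `cfg$evalue_max`, HSSP distance at
#' least `cfg$hssp_min` (alignments of <= 11 residues fail outright), and
#' alignment length at least `cfg$match_len_frac_min` of the shorter (or,
#' configurably, longer) of the two sequence lengths. The global-identity
#' requirement is applied later, on reciprocal-best-hit edges, where both
#' sequences are in hand.
#'
#' @param hits a hit table from [read_hit_table()].
#' @param cfg an [analysis_config()].
#' @return the retained subset of `hits`.
#' @export
filter_hits <- function(hits, cfg = analysis_config()) {
  hits <- validate_hit_table(hits)
  if (any(is.na(hits$qlen) | is.na(hits$slen)))
    ex_stop("filter_hits: qlen/slen required for the match-length test; ",
            "first incomplete record: ",
            hits$query[which(is.na(hits$qlen) | is.na(hits$slen))[1]], " -> ",
            hits$subject[which(is.na(hits$qlen) | is.na(hits$slen))[1]])
  denom <- if (cfg$match_len_denom == "shorter")
    pmin(hits$qlen, hits$slen) else pmax(hits$qlen, hits$slen)
  keep <- hits$evalue <= cfg$evalue_max &
    hits$length > 11 &
    hits$length >= cfg$match_len_frac_min * denom
  keep[keep] <- hssp_distance(hits$pident[keep], hits$length[keep]) >=
    cfg$hssp_min
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reciprocal-best-hit homology graph
#'
#' For every (query protein, subject genome) the best hit is the one with
#' the highest bit score (ties: lower E-value, then lexicographically
#' smallest subject id). An undirected edge joins two proteins of different
#' genomes iff each is the other's best hit. When `sequences` are supplied,
#' edges are additionally required to reach
#' `cfg$global_identity_min` percent global identity; otherwise a local
#' proxy `pident * length / max(qlen, slen)` is used and noted in the graph
#' attributes. Edge weight is the mean of the two directed bit scores.
#'
#' @param hits a filtered hit table.
#' @param cfg an [analysis_config()].
#' @param sequences optional named character vector (or `AAStringSet`) of
#'   protein sequences for the exact global-identity test.
#' @return an [igraph::graph] with vertex attribute `genome` and edge
#'   attributes `weight` (mean bit score) and `identity`.
#' @export
reciprocal_best_hits <- function(hits, cfg = analysis_config(),
                                 sequences = NULL) {
  hits <- validate_hit_table(hits)
  hits <- hits[hits$query_genome != hits$subject_genome, , drop = FALSE]
  if (nrow(hits)) {
    # deterministic best-hit choice per (query, subject genome)
    ord <- order(hits$query, hits$subject_genome, -hits$bitscore,
                 hits$evalue, hits$subject)
    hits <- hits[ord, , drop = FALSE]
    first <- !duplicated(paste(hits$query, hits$subject_genome, sep = "\r"))
    best <- hits[first, , drop = FALSE]
  } else best <- hits
  fwd <- paste(best$query, best$subject, sep = "\r")
  rev <- paste(best$subject, best$query, sep = "\r")
  mutual <- fwd %in% rev
  eg <- best[mutual & best$query < best$subject, , drop = FALSE]
  # weight: mean of the two directed bit scores
  back <- best[match(paste(eg$subject, eg$query, sep = "\r"), fwd),
               , drop = FALSE]
  weight <- (eg$bitscore + back$bitscore) / 2
  approx_identity <- FALSE
  if (nrow(eg)) {
    if (!is.null(sequences)) {
      seqs <- as.character(sequences)
      idy <- mapply(function(a, b) global_identity(seqs[[a]], seqs[[b]]),
                    eg$query, eg$subject)
    } else {
      approx_identity <- TRUE
      idy <- eg$pident * eg$length / pmax(eg$qlen, eg$slen)
    }
    keep <- idy >= cfg$global_identity_min
    eg <- eg[keep, , drop = FALSE]
    weight <- weight[keep]
    idy <- idy[keep]
  } else idy <- numeric(0)
  ids <- sort(unique(c(hits$query, hits$subject)))
  genome <- c(hits$query_genome, hits$subject_genome)[
    match(ids, c(hits$query, hits$subject))]
  g <- igraph::graph_from_data_frame(
    data.frame(from = eg$query, to = eg$subject,
               weight = weight, identity = idy,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = ids, genome = genome,
                          stringsAsFactors = FALSE)
  )
  igraph::graph_attr(g, "identity_approximated") <- approx_identity
  g
}

#' Markov clustering (MCL) of a homology graph
#'
#' Standard dense MCL iteration on the weighted adjacency matrix with
#' self-loops (each vertex's loop weight is its maximum incident edge
#' weight, 1 for isolated vertices): columns are normalized to stochastic,
#' then expansion (matrix squaring) alternates with inflation (entrywise
#' power `inflation`, renormalized) until the largest entry change drops
#' below `tol` or `max_iter` rounds. Clusters are the connected components
#' of the converged matrix's support.
#'
#' @param graph an [igraph::graph] with edge `weight`s.
#' @param inflation inflation parameter, > 1.
#' @param tol convergence threshold on the max entry change.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   current clustering.
#' @return a `data.frame` with columns `protein`, `cluster` (ids `COG0001`,
#'   ... ordered by decreasing size, ties by smallest member).
#' @export
mcl_cluster <- function(graph, inflation = 1.8, tol = 1e-8, max_iter = 200) {
  if (inflation <= 1) ex_stop("mcl_cluster: inflation must be > 1")
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (n == 0) return(data.frame(protein = character(0), cluster = character(0),
                                stringsAsFactors = FALSE))
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = FALSE)
  loops <- apply(A, 1, max)
  diag(A) <- ifelse(loops > 0, loops, 1)
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    ex_warn("mcl_cluster: not converged after ", max_iter,
            " iterations; emitting current clustering")
  support <- (M > 1e-6) | (t(M) > 1e-6)
  gsup <- igraph::graph_from_adjacency_matrix(support, mode = "undirected",
                                              diag = FALSE)
  comp <- igraph::components(gsup)$membership
  # stable cluster ids: order by decreasing size, then smallest member id
  sizes <- table(comp)
  firsts <- tapply(ids, comp, min)
  ord <- order(-as.integer(sizes), firsts)
  rank <- match(comp, as.integer(names(sizes))[ord])
  data.frame(protein = ids,
             cluster = sprintf("COG%04d", rank),
             stringsAsFactors = FALSE)
}

#' Assemble the presence/absence (copy count) matrix from a clustering
#'
#' @param clusters a `data.frame` with columns `protein`, `cluster`.
#' @param genome_map named character vector, protein id -> genome label, or
#'   `NULL` if `clusters` already has a `genome` column.
#' @param genomes label set for the rows; genomes without any clustered
#'   protein get (with a warning) an all-zero row, retained until
#'   [completeness_filter()].
#' @return an integer genomes x clusters matrix with attribute
#'   `single_copy_fraction`: the fraction of cluster-genome incidences
#'   represented by exactly one gene copy.
#' @export
assemble_matrix <- function(clusters, genome_map = NULL, genomes = NULL) {
  if (is.null(clusters$genome)) {
    if (is.null(genome_map))
      ex_stop("assemble_matrix: need a genome column or genome_map")
    missing <- setdiff(clusters$protein, names(genome_map))
    if (length(missing))
      ex_stop("assemble_matrix: no genome for protein(s): ",
              paste(head(missing, 5), collapse = ", "))
    clusters$genome <- unname(genome_map[clusters$protein])
  }
  genomes <- genomes %||% sort(unique(clusters$genome))
  empty <- setdiff(genomes, clusters$genome)
  if (length(empty))
    ex_warn("assemble_matrix: genome(s) with zero clustered proteins: ",
            paste(head(empty, 5), collapse = ", "))
  cl <- sort(unique(clusters$cluster))
  m <- matrix(0L, length(genomes), length(cl),
              dimnames = list(genomes, cl))
  tabs <- table(factor(clusters$genome, levels = genomes),
                factor(clusters$cluster, levels = cl))
  m[] <- as.integer(tabs)
  present <- m > 0
  attr(m, "single_copy_fraction") <-
    if (any(present)) sum(m[present] == 1L) / sum(present) else NA_real_
  m
}

#' Drop incomplete genomes by reference-core content
#'
#' The reference core is the set of clusters present in every genome of
#' `complete_genomes`. A genome is retained when it possesses at least
#' `ceiling(min_fraction * |reference core|)` of those clusters.
#'
#' @param m a presence/absence count matrix.
#' @param complete_genomes labels of the trusted (complete) genomes.
#' @param min_fraction required fraction of the reference core.
#' @return the filtered matrix, with attribute `report`: a list holding the
#'   reference-core size, the required count, and the per-genome tally.
#' @export
completeness_filter <- function(m, complete_genomes,
                                min_fraction = 0.957) {
  m <- validate_presence_absence(m)
  if (!length(complete_genomes))
    ex_stop("completeness_filter: complete_genomes is empty")
  missing <- setdiff(complete_genomes, rownames(m))
  if (length(missing))
    ex_stop("completeness_filter: unknown genome(s): ",
            paste(head(missing, 5), collapse = ", "))
  ref <- colnames(m)[colSums(m[complete_genomes, , drop = FALSE] > 0) ==
                       length(complete_genomes)]
  if (!length(ref))
    ex_stop("completeness_filter: reference core is empty")
  required <- as.integer(ceiling(min_fraction * length(ref)))
  tally <- rowSums(m[, ref, drop = FALSE] > 0)
  keep <- tally >= required
  out <- m[keep, , drop = FALSE]
  attr(out, "report") <- list(
    reference_core_size = length(ref),
    required_count = required,
    per_genome = tally,
    dropped = rownames(m)[!keep]
  )
  out
}

#' Partition clusters into core and pan sets
#'
#' Core clusters are present in every genome; pan clusters are present in
#' at least two genomes (so, with two or more genomes, the core is a subset
#' of the pan). Clusters found in exactly one genome are genome-unique and
#' belong to neither set.
#'
#' @param m a presence/absence count matrix.
#' @return a list with character vectors `core`, `pan`, `unique`.
#' @export
core_pan_partition <- function(m) {
  m <- validate_presence_absence(m)
  if (!nrow(m) || !ncol(m)) ex_stop("core_pan_partition: empty matrix")
  npres <- colSums(m > 0)
  list(core = colnames(m)[npres == nrow(m)],
       pan = colnames(m)[npres >= 2],
       unique = colnames(m)[npres == 1])
}

#' Choose a representative gene copy within a cluster
#'
#' When a genome contributes several gene copies to one cluster, the copy
#' kept for the concatenated alignment is chosen by, in order: (i) fewest
#' degenerate bases (`N`), (ii) lowest average pairwise distance to the
#' cluster's other genes (p-distance on global pairwise alignments),
#' (iii) length closest to the median length of the cluster's genes;
#' remaining ties go to the lexicographically smallest gene id.
#'
#' @param candidates named character vector of the genome's candidate gene
#'   sequences (names are gene ids).
#' @param peers named character vector of the cluster's other sequences
#'   (may be empty, in which case criterion (ii) is skipped).
#' @return the chosen gene id.
#' @export
choose_representative <- function(candidates, peers = character(0)) {
  if (!length(candidates)) ex_stop("choose_representative: no candidates")
  if (length(candidates) == 1L) return(names(candidates))
  n_deg <- vapply(candidates, function(s)
    sum(strsplit(toupper(s), "")[[1]] == "N"), numeric(1))
  avg_dist <- if (length(peers)) {
    vapply(candidates, function(s)
      mean(vapply(peers, function(p) 1 - pdist_pair(s, p), numeric(1))),
      numeric(1))
  } else rep(0, length(candidates))
  med_len <- stats::median(nchar(c(candidates, peers)))
  len_dev <- abs(nchar(candidates) - med_len)
  ord <- order(n_deg, avg_dist, len_dev, names(candidates))
  names(candidates)[ord[1]]
}

# fraction of identical columns on a global pairwise DNA alignment
pdist_pair <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  sum(p == s & p != "-") / length(p)
}

#' Drop gap-rich alignment columns
#'
#' Removes columns whose gap fraction strictly exceeds `max_gap_fraction`
#' (so a column at exactly the threshold is kept). Gaps are `-` and `.`.
#'
#' @param alignment a named character vector of equal-length aligned rows,
#'   or an `XStringSet`.
#' @param max_gap_fraction maximum tolerated gap fraction per column.
#' @return the trimmed alignment as a named character vector; the surviving
#'   column indices are in attribute `kept_columns`.
#' @export
trim_alignment_columns <- function(alignment, max_gap_fraction = 0.90) {
  aln <- as.character(alignment)
  if (length(unique(nchar(aln))) != 1L)
    ex_stop("trim_alignment_columns: ragged alignment")
  rows <- strsplit(aln, "")
  mat <- do.call(rbind, rows)
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= max_gap_fraction)
  out <- vapply(rows, function(r) paste(r[keep], collapse = ""), character(1))
  names(out) <- names(aln)
  attr(out, "kept_columns") <- keep
  out
}
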