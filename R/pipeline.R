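#' Run the full exclusivity analysis pipeline
#'
#' Chains the package's stages over plain-text inputs, skipping stages
#' whose inputs are absent (with a log line), and writes every intermediate
#' as a documented plain-text file plus a JSON run manifest:
#'
#' 1. orthology (needs `hits`): filter, reciprocal best hits, MCL,
#'    presence/absence assembly -> `pa.tsv`;
#' 2. distances (needs `gene_trees`): per-gene patristic matrices averaged
#'    -> `avg_patristic.tsv`, core UPGMA tree -> `core_upgma.nwk`;
#' 3. pan tree (needs presence/absence): Jaccard + UPGMA -> `pan.nwk`;
#' 4. congruence (needs both trees): RF distance, maximum, random-tree
#'    expectation and log10 tail probability -> `congruence.tsv`;
#' 5. gain/loss (needs pan matrix + core tree): Fitch mapping ->
#'    `gainloss.tsv`;
#' 6. exclusivity (needs distances): clade records on the pan tree (or the
#'    UPGMA tree of the distances) -> `exclusivity.tsv`;
#' 7. delimitation (needs distances + `pair_table`): species partition ->
#'    `species.tsv`, `summary.json`.
#'
#' @param gene_trees paths to newick gene trees (or a directory of
#'   `*.nwk`), or `NULL`.
#' @param pa path to a presence/absence TSV, or `NULL` (derived from
#'   `hits` when those are given).
#' @param pair_table path to an ANI/AF TSV, or `NULL`.
#' @param hits path to a BLAST tabular TSV with qlen/slen and genome
#'   columns, or `NULL`.
#' @param cfg an [analysis_config()].
#' @param out_dir output directory (created if needed).
#' @return the run manifest (list), invisibly; written as `manifest.json`.
#' @export
run_pipeline <- function(gene_trees = NULL, pa = NULL, pair_table = NULL,
                         hits = NULL, cfg = analysis_config(),
                         out_dir = "exclutax_out") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs <- list(gene_trees = gene_trees, pa = pa,
                 pair_table = pair_table, hits = hits)
  outputs <- list()
  if (length(gene_trees) == 1 && dir.exists(gene_trees))
    gene_trees <- sort(list.files(gene_trees, pattern = "\\.nwk$",
                                  full.names = TRUE))

  pa_mat <- NULL
  if (!is.null(hits)) {
    ex_log("info", "orthology: filtering hits and clustering")
    ht <- filter_hits(read_hit_table(hits), cfg)
    graph <- reciprocal_best_hits(ht, cfg)
    clusters <- mcl_cluster(graph, inflation = cfg$mcl_inflation)
    gmap <- setNames(igraph::V(graph)$genome, igraph::V(graph)$name)
    pa_mat <- assemble_matrix(clusters, genome_map = gmap)
    outputs$clusters <- file.path(out_dir, "clusters.tsv")
    write.table(clusters, outputs$clusters, sep = "\t", quote = FALSE,
                row.names = FALSE)
    outputs$pa <- file.path(out_dir, "pa.tsv")
    write_presence_absence(pa_mat, outputs$pa)
  } else if (!is.null(pa)) {
    pa_mat <- read_presence_absence(pa)
  } else ex_log("info", "skipping orthology/presence-absence: no input")

  avg <- NULL
  core_tree <- NULL
  if (!is.null(gene_trees) && length(gene_trees)) {
    ex_log("info", "distances: averaging ", length(gene_trees),
           " gene trees")
    trees <- lapply(gene_trees, function(f) read_newick(file = f))
    avg <- average_matrices(lapply(trees, patristic_matrix))
    outputs$avg <- file.path(out_dir, "avg_patristic.tsv")
    write_distance_matrix(avg, outputs$avg)
    core_tree <- upgma(avg)$tree
    outputs$core_tree <- file.path(out_dir, "core_upgma.nwk")
    write_newick(core_tree, outputs$core_tree)
  } else ex_log("info", "skipping distances: no gene trees")

  pan_tree <- NULL
  if (!is.null(pa_mat)) {
    ex_log("info", "pan tree: Jaccard + UPGMA on ", ncol(pa_mat),
           " clusters")
    pan_tree <- upgma(jaccard_matrix(pa_mat))$tree
    outputs$pan_tree <- file.path(out_dir, "pan.nwk")
    write_newick(pan_tree, outputs$pan_tree)
  }

  if (!is.null(core_tree) && !is.null(pan_tree)) {
    rf <- robinson_foulds(core_tree, pan_tree)
    null <- random_rf_null(length(core_tree$tip.label))
    cong <- data.frame(rf = rf, max_rf = null$max_rf,
                       expected_rf = null$expected_rf,
                       log10_p_le = null$log10_tail(rf))
    outputs$congruence <- file.path(out_dir, "congruence.tsv")
    write.table(cong, outputs$congruence, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  if (!is.null(core_tree) && !is.null(pa_mat)) {
    gl <- map_pan_genome(core_tree, pa_mat)
    outputs$gainloss <- file.path(out_dir, "gainloss.tsv")
    write.table(
      data.frame(total = gl$total, gains = gl$gains, losses = gl$losses,
                 branches = gl$branch_count,
                 gains_per_branch = gl$per_branch_average["gains"],
                 losses_per_branch = gl$per_branch_average["losses"]),
      outputs$gainloss, sep = "\t", quote = FALSE, row.names = FALSE)
  }

  if (!is.null(avg)) {
    score_tree <- if (!is.null(pan_tree)) pan_tree else upgma(avg)$tree
    ann <- annotate_tree(score_tree, avg, slack = cfg$exclusivity_slack)
    outputs$exclusivity <- file.path(out_dir, "exclusivity.tsv")
    write.table(ann$records, outputs$exclusivity, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(avg) && !is.null(pair_table)) {
    pairs <- read_pair_similarity(pair_table,
                                  symmetrize = cfg$pair_symmetrize)
    part <- delimit_species(avg, pairs, cfg)
    outputs$species <- file.path(out_dir, "species.tsv")
    write.table(part$table, outputs$species, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rep <- split_report(part, pairs, cfg)
    outputs$summary <- file.path(out_dir, "summary.json")
    jsonlite::write_json(
      c(summarize_partition(part),
        list(split_ratio = rep$ratio, n_meeting = rep$n_meeting,
             n_split = rep$n_split)),
      outputs$summary, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else if (!is.null(pair_table) && is.null(avg)) {
    ex_stop("run_pipeline: delimitation requested (pair_table given) but ",
            "no distances available: supply gene_trees")
  }

  manifest <- list(
    package = "exclutax",
    version = as.character(utils::packageVersion("exclutax")),
    inputs = lapply(Filter(Negate(is.null), inputs), function(p) {
      files <- if (length(p) == 1 && dir.exists(p))
        list.files(p, full.names = TRUE) else p
      list(path = p, md5 = unname(tools::md5sum(files[file.exists(files)])))
    }),
    config = unclass(cfg),
    seed = cfg$seed,
    outputs = outputs
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
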