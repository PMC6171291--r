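#' Read a pairwise protein hit table (BLAST tabular format)
#'
#' Accepts the conventional 12-column tabular output
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), optionally extended by `qlen` and `slen` columns
#' (13-14) and by query/subject genome columns (15-16). When genome columns
#' are absent a `genome_map` (named character vector, protein id -> genome)
#' must cover every sequence id.
#'
#' @param file path to the TSV (no header).
#' @param genome_map named character vector mapping protein ids to genome
#'   labels; ignored when the table carries genome columns.
#' @return a `data.frame` with columns `query`, `subject`, `pident`,
#'   `length`, `evalue`, `bitscore`, `qlen`, `slen` (NA when absent),
#'   `query_genome`, `subject_genome`.
#' @export
read_hit_table <- function(file, genome_map = NULL) {
  tab <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12)
    ex_stop("hit table: expected at least 12 tab-separated columns, got ",
            ncol(tab))
  hits <- data.frame(
    query = as.character(tab[[1]]), subject = as.character(tab[[2]]),
    pident = as.numeric(tab[[3]]), length = as.integer(tab[[4]]),
    evalue = as.numeric(tab[[11]]), bitscore = as.numeric(tab[[12]]),
    qlen = if (ncol(tab) >= 13) as.integer(tab[[13]]) else NA_integer_,
    slen = if (ncol(tab) >= 14) as.integer(tab[[14]]) else NA_integer_,
    stringsAsFactors = FALSE
  )
  if (ncol(tab) >= 16) {
    hits$query_genome <- as.character(tab[[15]])
    hits$subject_genome <- as.character(tab[[16]])
  } else {
    if (is.null(genome_map))
      ex_stop("hit table: no genome columns and no genome_map supplied")
    ids <- unique(c(hits$query, hits$subject))
    missing <- setdiff(ids, names(genome_map))
    if (length(missing))
      ex_stop("hit table: no genome assignment for sequence id(s): ",
              paste(head(missing, 5), collapse = ", "))
    hits$query_genome <- unname(genome_map[hits$query])
    hits$subject_genome <- unname(genome_map[hits$subject])
  }
  validate_hit_table(hits)
}

validate_hit_table <- function(hits) {
  need <- c("query", "subject", "pident", "length", "evalue", "bitscore",
            "query_genome", "subject_genome")
  miss <- setdiff(need, names(hits))
  if (length(miss))
    ex_stop("hit table: missing column(s): ", paste(miss, collapse = ", "))
  if (any(hits$pident < 0 | hits$pident > 100))
    ex_stop("hit table: percent identity outside [0, 100]")
  if (any(hits$length < 1))
    ex_stop("hit table: alignment length must be positive")
  if (any(hits$evalue < 0))
    ex_stop("hit table: negative E-value")
  hits
}

#' Read a pairwise genome similarity table (ANI/AF)
#'
#' Input is a TSV with columns genome A, genome B, ANI (percent) and AF
#' (fraction); a header line is detected and skipped. ANI tools report two
#' directed values per genome pair; directions are combined into one record
#' per unordered pair by the configured policy (arithmetic mean by default,
#' minimum as the conservative alternative). A pair seen in only one
#' direction is kept as-is with a warning.
#'
#' @param file path to the TSV.
#' @param symmetrize `"mean"` or `"min"`.
#' @return a `data.frame` with columns `genome_a`, `genome_b` (sorted within
#'   each row), `ani`, `af`, one row per unordered pair.
#' @export
read_pair_similarity <- function(file, symmetrize = c("mean", "min")) {
  symmetrize <- match.arg(symmetrize)
  first <- strsplit(readLines(file, n = 1), "\t")[[1]]
  header <- length(first) >= 4 && is.na(suppressWarnings(as.numeric(first[3])))
  tab <- read.delim(file, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4)
    ex_stop("pair similarity: expected 4 columns (A, B, ANI, AF)")
  pairs <- data.frame(a = as.character(tab[[1]]), b = as.character(tab[[2]]),
                      ani = as.numeric(tab[[3]]), af = as.numeric(tab[[4]]),
                      stringsAsFactors = FALSE)
  symmetrize_pairs(pairs, symmetrize)
}

symmetrize_pairs <- function(pairs, policy = c("mean", "min")) {
  policy <- match.arg(policy)
  if (any(is.na(pairs$ani)) || any(pairs$ani < 0 | pairs$ani > 100))
    ex_stop("pair similarity: ANI outside [0, 100]")
  if (any(is.na(pairs$af)) || any(pairs$af < 0 | pairs$af > 1))
    ex_stop("pair similarity: AF outside [0, 1]")
  if (any(pairs$a == pairs$b))
    ex_stop("pair similarity: self-pair present")
  ga <- pmin(pairs$a, pairs$b)
  gb <- pmax(pairs$a, pairs$b)
  key <- paste(ga, gb, sep = "\r")
  cnt <- table(key)
  if (any(cnt > 2))
    ex_stop("pair similarity: pair recorded more than twice: ",
            sub("\r", " / ", names(cnt)[cnt > 2][1]))
  # a pair listed twice in the SAME direction is a duplicate, not a reverse
  dirkey <- paste(pairs$a, pairs$b, sep = "\r")
  if (anyDuplicated(dirkey))
    ex_stop("pair similarity: duplicate directed record: ",
            sub("\r", " -> ", dirkey[duplicated(dirkey)][1]))
  if (any(cnt == 1))
    ex_warn("pair similarity: ", sum(cnt == 1),
            " pair(s) present in one direction only; using that direction")
  comb <- if (policy == "mean") function(x) mean(x) else function(x) min(x)
  agg_ani <- tapply(pairs$ani, key, comb)
  agg_af <- tapply(pairs$af, key, comb)
  keys <- sort(names(agg_ani))
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    genome_a = vapply(parts, `[`, character(1), 1),
    genome_b = vapply(parts, `[`, character(1), 2),
    ani = unname(agg_ani[keys]), af = unname(agg_af[keys]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' @param pairs a symmetrized pair-similarity `data.frame`.
#' @rdname read_pair_similarity
#' @export
write_pair_similarity <- function(pairs, file) {
  write.table(pairs, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

# fast lookup matrices (ANI and AF keyed by genome labels, NA where missing)
pair_lookup <- function(pairs, genomes) {
  ani <- matrix(NA_real_, length(genomes), length(genomes),
                dimnames = list(genomes, genomes))
  af <- ani
  keep <- pairs$genome_a %in% genomes & pairs$genome_b %in% genomes
  p <- pairs[keep, , drop = FALSE]
  ia <- match(p$genome_a, genomes)
  ib <- match(p$genome_b, genomes)
  ani[cbind(ia, ib)] <- ani[cbind(ib, ia)] <- p$ani
  af[cbind(ia, ib)] <- af[cbind(ib, ia)] <- p$af
  list(ani = ani, af = af)
}
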