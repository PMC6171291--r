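#' Validate a labeled distance matrix
#'
#' The package carries distance matrices as plain numeric matrices with
#' identical row and column labels. A valid matrix is square, symmetric to
#' `tol`, has a zero diagonal, finite nonnegative entries and unique labels.
#'
#' @param d a numeric matrix with dimnames.
#' @param tol absolute tolerance for symmetry and diagonal checks.
#' @return `d`, with the symmetric average enforced exactly, invisibly
#'   validated.
#' @export
validate_dist_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || !is.numeric(d)) ex_stop("distance: not a numeric matrix")
  if (nrow(d) != ncol(d)) ex_stop("distance: matrix is not square")
  labs <- rownames(d)
  if (is.null(labs) || is.null(colnames(d)))
    ex_stop("distance: matrix must carry row and column labels")
  if (!identical(labs, colnames(d)))
    ex_stop("distance: row and column labels differ")
  if (anyDuplicated(labs)) ex_stop("distance: duplicated labels")
  if (any(!is.finite(d))) ex_stop("distance: non-finite entries")
  if (any(d < 0)) ex_stop("distance: negative entries")
  if (max(abs(d - t(d))) > tol)
    ex_stop("distance: asymmetry exceeds tolerance ", tol)
  if (max(abs(diag(d))) > tol)
    ex_stop("distance: nonzero diagonal")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Read and write distance matrices
#'
#' Two plain-text dialects are supported: TSV with a header row and a
#' leading label column (the canonical output format), and square PHYLIP
#' with a leading taxon count.
#'
#' @param file path to the matrix file.
#' @param format `"auto"` sniffs the dialect (a first line that is a single
#'   integer means PHYLIP), or `"tsv"` / `"phylip"`.
#' @return a validated labeled distance matrix.
#' @export
read_distance_matrix <- function(file, format = c("auto", "tsv", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto")
    format <- if (grepl("^\\s*\\d+\\s*$", lines[1])) "phylip" else "tsv"
  if (format == "phylip") {
    n <- as.integer(trimws(lines[1]))
    if (length(lines) - 1L != n)
      ex_stop("distance: PHYLIP header says ", n, " taxa but ",
              length(lines) - 1L, " rows follow")
    fields <- strsplit(trimws(lines[-1]), "\\s+")
    labs <- vapply(fields, `[`, character(1), 1)
    vals <- lapply(fields, function(f) as.numeric(f[-1]))
    if (any(lengths(vals) != n))
      ex_stop("distance: PHYLIP row with wrong number of entries")
    d <- do.call(rbind, vals)
    dimnames(d) <- list(labs, labs)
  } else {
    tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
    labs <- as.character(tab[[1]])
    d <- as.matrix(tab[, -1, drop = FALSE])
    mode(d) <- "numeric"
    rownames(d) <- labs
    if (!identical(colnames(d), labs))
      ex_stop("distance: TSV header labels do not match the label column")
  }
  validate_dist_matrix(d)
}

#' @param d a validated distance matrix.
#' @rdname read_distance_matrix
#' @export
write_distance_matrix <- function(d, file, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  d <- validate_dist_matrix(d)
  if (format == "tsv") {
    tab <- data.frame(label = rownames(d),
                      apply(d, 2, fmt_num),
                      check.names = FALSE, stringsAsFactors = FALSE)
    colnames(tab) <- c("label", colnames(d))
    write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(as.character(nrow(d)), con)
    for (i in seq_len(nrow(d)))
      writeLines(paste(c(rownames(d)[i], fmt_num(d[i, ])), collapse = " "),
                 con)
  }
  invisible(file)
}

#' Read a gene presence/absence matrix
#'
#' Input is a TSV whose first column holds genome labels and whose remaining
#' columns hold per-cluster copy counts (0 = absent; counts above 1 record
#' paralogs). Counts must be nonnegative integers. The binary presence view
#' is `counts > 0`.
#'
#' @param file path to the TSV.
#' @return an integer matrix, genomes x clusters.
#' @export
read_presence_absence <- function(file) {
  tab <- read.delim(file, check.names = FALSE, stringsAsFactors = FALSE)
  genomes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genomes
  validate_presence_absence(m)
}

validate_presence_absence <- function(m) {
  if (anyDuplicated(rownames(m)))
    ex_stop("presence/absence: duplicated genome labels")
  if (anyDuplicated(colnames(m)))
    ex_stop("presence/absence: duplicated cluster labels")
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    ex_stop("presence/absence: counts must be nonnegative integers")
  storage.mode(m) <- "integer"
  m
}

#' @param m an integer genomes x clusters count matrix.
#' @rdname read_presence_absence
#' @export
write_presence_absence <- function(m, file) {
  m <- validate_presence_absence(m)
  tab <- data.frame(genome = rownames(m), m,
                    check.names = FALSE, stringsAsFactors = FALSE)
  colnames(tab) <- c("genome", colnames(m))
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
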