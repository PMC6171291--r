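#' Analysis configuration
#'
#' Collects every tunable threshold of the analysis in one validated object.
#' Defaults are the conventional values used throughout: BLAST E-value cutoff
#' 1e-3, HSSP distance cutoff 20, match length at least 30% of the shorter
#' sequence, 60% global amino-acid identity, MCL inflation 1.8, genome
#' completeness at 95.7% of the reference core, alignment columns dropped
#' above 90% gaps, and the joint species threshold of ANI >= 96.5% with
#' AF >= 0.60.
#'
#' @param evalue_max maximum BLAST E-value for a candidate hit.
#' @param hssp_min minimum HSSP distance (percent identity above the
#'   length-dependent homology threshold curve).
#' @param match_len_frac_min minimum alignment length as a fraction of the
#'   shorter of the two sequences.
#' @param global_identity_min minimum global amino-acid identity (percent)
#'   for a reciprocal-best-hit edge.
#' @param mcl_inflation Markov clustering inflation parameter (> 1).
#' @param core_fraction_min fraction of the reference core a genome must
#'   possess to be retained.
#' @param gap_col_max maximum tolerated gap fraction in an alignment column.
#' @param ani_min,af_min joint species similarity thresholds; ANI is in
#'   percent, AF is a fraction in [0, 1].
#' @param exclusivity_slack relaxation of the exclusivity requirement: a
#'   group qualifies when its score exceeds `-exclusivity_slack` (0 demands
#'   strictly positive scores; 0.01 is the relaxed variant).
#' @param linkage `"single"` (the group's members form one connected
#'   single-linkage cluster of the ANI/AF threshold graph, so each member
#'   meets the threshold with at least one other member and the group is
#'   not a union of mutually dissimilar blocks), `"complete"` (every
#'   within-group pair meets the threshold), or `"single_literal"` (only
#'   requires each member to meet the threshold with at least one other
#'   member, which admits groups whose threshold graph is disconnected).
#' @param match_len_denom denominator convention for the match-length
#'   fraction: shorter or longer sequence.
#' @param pair_symmetrize how two directed ANI/AF measurements of the same
#'   genome pair are combined: arithmetic `"mean"` or `"min"`.
#' @param seed integer seed recorded with the run; `NULL` leaves the RNG
#'   untouched.
#' @return an object of class `"exclutax_config"` (a validated named list).
#' @seealso [write_config()], [read_config()]
#' @export
#' @examples
#' cfg <- analysis_config(exclusivity_slack = 0.01)
#' cfg$ani_min
analysis_config <- function(evalue_max = 1e-3,
                            hssp_min = 20,
                            match_len_frac_min = 0.30,
                            global_identity_min = 60,
                            mcl_inflation = 1.8,
                            core_fraction_min = 0.957,
                            gap_col_max = 0.90,
                            ani_min = 96.5,
                            af_min = 0.60,
                            exclusivity_slack = 0,
                            linkage = c("single", "complete",
                                        "single_literal"),
                            match_len_denom = c("shorter", "longer"),
                            pair_symmetrize = c("mean", "min"),
                            seed = NULL) {
  linkage <- match.arg(linkage)
  match_len_denom <- match.arg(match_len_denom)
  pair_symmetrize <- match.arg(pair_symmetrize)
  chk <- function(val, lo, hi, what) {
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val < lo || val > hi)
      ex_stop("config: ", what, " must be a number in [", lo, ", ", hi, "]")
  }
  chk(evalue_max, 0, Inf, "evalue_max")
  chk(hssp_min, -Inf, 100, "hssp_min")
  chk(match_len_frac_min, 0, 1, "match_len_frac_min")
  chk(global_identity_min, 0, 100, "global_identity_min")
  if (!is.numeric(mcl_inflation) || mcl_inflation <= 1)
    ex_stop("config: mcl_inflation must be > 1")
  chk(core_fraction_min, 0, 1, "core_fraction_min")
  chk(gap_col_max, 0, 1, "gap_col_max")
  chk(ani_min, 0, 100, "ani_min")
  chk(af_min, 0, 1, "af_min")
  chk(exclusivity_slack, 0, Inf, "exclusivity_slack")
  if (!is.null(seed)) {
    if (!is_count(seed)) ex_stop("config: seed must be a nonnegative integer")
    seed <- as.integer(seed)
  }
  structure(list(
    evalue_max = evalue_max, hssp_min = hssp_min,
    match_len_frac_min = match_len_frac_min,
    global_identity_min = global_identity_min,
    mcl_inflation = mcl_inflation,
    core_fraction_min = core_fraction_min,
    gap_col_max = gap_col_max,
    ani_min = ani_min, af_min = af_min,
    exclusivity_slack = exclusivity_slack,
    linkage = linkage, match_len_denom = match_len_denom,
    pair_symmetrize = pair_symmetrize, seed = seed
  ), class = "exclutax_config")
}

#' @export
print.exclutax_config <- function(x, ...) {
  cat("exclutax analysis configuration\n")
  for (k in names(x)) {
    v <- x[[k]]
    cat(sprintf("  %-20s %s\n", k, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}

#' Write or read a configuration as a plain-text key=value file
#'
#' @param cfg an [analysis_config()] object.
#' @param path file path.
#' @return `read_config()` returns an `"exclutax_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "exclutax_config"))
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, "=", if (is.null(v)) "" else
      if (is.numeric(v)) fmt_num(v) else as.character(v))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*[#;]", lines)]
  kv <- regmatches(lines, regexec("^\\s*([^=]+?)\\s*=\\s*(.*?)\\s*$", lines))
  bad <- lengths(kv) != 3L
  if (any(bad)) ex_stop("config: malformed line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  args <- list()
  defaults <- analysis_config()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (!k %in% names(defaults)) ex_stop("config: unknown key '", k, "'")
    v <- vals[i]
    args[[k]] <- if (k %in% c("linkage", "match_len_denom", "pair_symmetrize"))
      v
    else if (!nzchar(v)) NULL
    else as.numeric(v)
  }
  do.call(analysis_config, args)
}
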