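#' Read and write trees in newick format
#'
#' Thin validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Reading checks bracket balance (reporting the
#' character offset of the first imbalance), requires a terminating
#' semicolon, and rejects duplicated leaf labels and negative branch
#' lengths.
#'
#' @param text a newick string; exactly one of `text`/`file`.
#' @param file path to a newick file containing a single tree.
#' @return a `"phylo"` tree.
#' @export
#' @examples
#' tr <- read_newick("((A:1,B:1):2,C:3);")
#' write_newick(tr)
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text) == is.null(file))
    ex_stop("read_newick: supply exactly one of text= or file=")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE),
                                    collapse = "")
  text <- trimws(text)
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        ex_stop("read_newick: unbalanced ')' at character ", i)
    }
  }
  if (depth != 0L)
    ex_stop("read_newick: ", depth, " unclosed '(' at character ",
            length(chars))
  if (!grepl(";\\s*$", text))
    ex_stop("read_newick: missing terminating ';' at character ",
            length(chars))
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) ex_stop("read_newick: ape failed to parse the string")
  validate_tree(tree)
  tree
}

#' @param tree a `"phylo"` object.
#' @param digits significant digits for branch lengths.
#' @rdname read_newick
#' @export
write_newick <- function(tree, file = NULL, digits = 10) {
  validate_tree(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(file)
}

# invariants every tree consumed or produced by the package must satisfy
validate_tree <- function(tree, lengths = FALSE) {
  if (!inherits(tree, "phylo")) ex_stop("expected a 'phylo' tree")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    ex_stop("tree validation: duplicate leaf label(s): ",
            paste(unique(dup), collapse = ", "))
  if (!is.null(tree$edge.length)) {
    bad <- which(!is.na(tree$edge.length) & tree$edge.length < 0)
    if (length(bad))
      ex_stop("tree validation: negative branch length on edge ", bad[1])
  }
  if (lengths) {
    if (is.null(tree$edge.length))
      ex_stop("tree validation: branch lengths required but absent")
    bad <- which(is.na(tree$edge.length))
    if (length(bad))
      ex_stop("tree validation: missing branch length on edge ", bad[1],
              " (", tree$edge[bad[1], 1], " -> ", tree$edge[bad[1], 2], ")")
  }
  invisible(tree)
}
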