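# Newick trees via ape.  Internal-node labels are interpreted as
# bootstrap support values in [0, 100]; unrooted trees follow ape's
# trifurcating-root representation.

#' Read a Newick tree
#'
#' @param text Newick string, or path to a file containing one tree
#' @return ape `phylo`; internal-node labels (supports) on `node.label`
#' @export
readNewickTree <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text), collapse = "")
  text <- paste(text, collapse = "")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("Newick parse error: unbalanced parentheses")
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop("Newick parse error")
  phy
}

#' Write a Newick tree
#'
#' @param phy ape `phylo` (node labels written as internal labels)
#' @param path optional output file; if NULL the Newick string is
#'   returned
#' @return Newick string (invisibly when written to file)
#' @export
writeNewickTree <- function(phy, path = NULL) {
  s <- ape::write.tree(phy, digits = 10)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Numeric bootstrap supports of internal nodes
#'
#' @param phy ape `phylo`
#' @return numeric vector aligned with internal nodes (NA where absent)
#' @export
nodeSupports <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}
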