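#' Newick gene-tree I/O
#'
#' Gene trees exchange as single Newick strings; leaves follow the
#' `"<species>|<gene>"` label convention so that two-species reconciliation
#' can recover the species of every leaf. Parsing is delegated to ape;
#' polytomies are accepted on read (reconciliation resolves them
#' deterministically, see [reconcile_species_overlap()]).
#'
#' @param path file containing one Newick tree.
#' @return an ape `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("Newick parse error: ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree could be read from ", path)
  if (inherits(tr, "multiPhylo")) tr <- tr[[1]]
  tr
}

#' @rdname read_newick
#' @param tree an ape `phylo` object.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Species of each leaf under the "species|gene" convention
#'
#' @param labels leaf labels.
#' @return character vector of species tags.
#' @export
leaf_species <- function(labels) {
  hit <- grepl("|", labels, fixed = TRUE)
  if (!all(hit))
    stop("leaf label(s) without a species tag ('species|gene'): ",
         paste(labels[!hit], collapse = ", "))
  sub("\\|.*$", "", labels)
}
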