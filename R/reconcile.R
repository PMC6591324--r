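# Species-overlap reconciliation and MRCA gain/loss accounting for
# two-species gene trees with "species|gene" leaf labels.

.tree_children <- function(tree) {
  split(tree$edge[, 2], factor(tree$edge[, 1],
                               levels = seq_len(ape::Ntip(tree) + tree$Nnode)))
}

.tips_under <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- .tree_children(tree)
  tips <- vector("list", nn)
  for (i in seq_len(ntip)) tips[[i]] <- i
  # postorder lists child edges before their parents: walk nodes bottom-up
  for (node in unique(tree$edge[ape::postorder(tree), 1])) {
    tips[[node]] <- unlist(tips[kids[[node]]])
  }
  tips
}

#' Label gene-tree nodes by species overlap
#'
#' For a rooted binary gene tree over at most two species, each internal
#' node is a duplication if the species sets of its two child subtrees
#' intersect, otherwise a speciation. Duplications are split into
#' `duplication_ancestral` (the node's subtree contains both species) and
#' `duplication_lineage` (single-species subtree). Polytomies are resolved
#' deterministically (left-branching) with a warning; unrooted input is
#' midpoint-rooted with a warning.
#'
#' @param tree an ape `phylo` with `"species|gene"` leaf labels.
#' @return the tree with `node.label` set to the reconciliation labels and
#'   attribute `species` (the species tags seen).
#' @export
reconcile_species_overlap <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved deterministically (left-branching)")
    tree <- ape::multi2di(tree, random = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    warning("unrooted input: applying midpoint rooting")
    if (is.null(tree$edge.length)) tree <- ape::compute.brlen(tree, 1)
    tree <- phangorn::midpoint(tree)
  }
  sp <- leaf_species(tree$tip.label)
  species <- sort(unique(sp))
  if (length(species) > 2)
    stop("species-overlap reconciliation supports at most 2 species; got: ",
         paste(species, collapse = ", "))
  ntip <- ape::Ntip(tree)
  tips <- .tips_under(tree)
  kids <- .tree_children(tree)
  labels <- character(tree$Nnode)
  for (node in (ntip + 1):(ntip + tree$Nnode)) {
    ch <- kids[[node]]
    sets <- lapply(ch, function(k) unique(sp[tips[[k]]]))
    own <- unique(sp[tips[[node]]])
    if (length(intersect(sets[[1]], sets[[2]])) > 0) {
      labels[node - ntip] <- if (length(own) == 2)
        "duplication_ancestral" else "duplication_lineage"
    } else {
      labels[node - ntip] <- "speciation"
    }
  }
  tree$node.label <- labels
  attr(tree, "species") <- species
  tree
}

#' MRCA units and per-species gain/loss from a reconciled tree
#'
#' Decomposes the reconciled tree into most-recent-common-ancestor (MRCA)
#' units - ancestral gene lineages present before the species split - such
#' that units partition all leaves: descending from the root, an ancestral
#' duplication splits into the units of its children; a speciation node
#' whose subtree holds both species is one unit; a maximal single-species
#' clade attached under an ancestral duplication is one unit (the other
#' species lost it). Within a unit, extra same-species leaves are
#' post-split gains. Per species the identity
#' `extant = units - losses + gains` is enforced by assertion.
#'
#' @param tree output of [reconcile_species_overlap()] (or a tree, which
#'   is reconciled first).
#' @param species optional character(2) naming the two species; defaults
#'   to the tags observed (a species absent from the tree gets zero
#'   extant and all-unit losses).
#' @return list `units` (count), `unit_leaves` (list of leaf-label
#'   vectors), and `summary`: data.frame with one row per species
#'   (`species`, `extant`, `gains`, `losses`, `mrca_units`).
#' @export
infer_gain_loss <- function(tree, species = NULL) {
  if (is.null(tree$node.label) ||
      !all(tree$node.label %in% c("speciation", "duplication_ancestral",
                                  "duplication_lineage")))
    tree <- reconcile_species_overlap(tree)
  sp <- leaf_species(tree$tip.label)
  if (is.null(species)) species <- sort(unique(sp))
  stopifnot(length(species) <= 2)
  ntip <- ape::Ntip(tree)
  tips <- .tips_under(tree)
  kids <- .tree_children(tree)
  node_label <- function(node) tree$node.label[node - ntip]
  units <- list()
  visit <- function(node) {
    if (node <= ntip) { units[[length(units) + 1]] <<- node; return(invisible()) }
    own <- unique(sp[tips[[node]]])
    if (length(own) == 1 || node_label(node) == "speciation") {
      units[[length(units) + 1]] <<- tips[[node]]
      return(invisible())
    }
    for (k in kids[[node]]) visit(k)
  }
  visit(ntip + 1L)
  # partition check: every leaf in exactly one unit
  all_tips <- sort(unlist(units))
  stopifnot(identical(all_tips, seq_len(ntip)))
  n_units <- length(units)
  summ <- do.call(rbind, lapply(species, function(x) {
    extant <- sum(sp == x)
    with_x <- sum(vapply(units, function(u) any(sp[u] == x), logical(1)))
    losses <- n_units - with_x
    gains <- extant - with_x
    stopifnot(extant == n_units - losses + gains, gains >= 0, losses >= 0)
    data.frame(species = x, extant = extant, gains = gains,
               losses = losses, mrca_units = n_units,
               stringsAsFactors = FALSE)
  }))
  list(units = n_units,
       unit_leaves = lapply(units, function(u) tree$tip.label[u]),
       summary = summ)
}

#' Solve the gain/loss accounting identity
#'
#' `extant = mrca - losses + gains`; given any three quantities the fourth
#' is returned. Negative solutions raise an inconsistency error.
#'
#' @param mrca,losses,gains,extant non-negative integers; exactly one NULL.
#' @return the missing quantity.
#' @examples
#' gainloss_from_counts(mrca = 55, losses = 13, extant = 59)  # gains = 17
#' @export
gainloss_from_counts <- function(mrca = NULL, losses = NULL, gains = NULL,
                                 extant = NULL) {
  args <- list(mrca = mrca, losses = losses, gains = gains, extant = extant)
  miss <- names(args)[vapply(args, is.null, logical(1))]
  if (length(miss) != 1)
    stop("exactly one of mrca/losses/gains/extant must be missing")
  given <- args[setdiff(names(args), miss)]
  if (any(unlist(given) < 0)) stop("counts must be non-negative")
  val <- switch(miss,
    gains = extant - mrca + losses,
    losses = gains - extant + mrca,
    extant = mrca - losses + gains,
    mrca = extant + losses - gains)
  if (val < 0)
    stop("inconsistent gain/loss accounting: ", miss, " would be ", val)
  val
}
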