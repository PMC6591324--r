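#' Pairwise protein distance
#'
#' Sequences are globally aligned first (BLOSUM62 defaults); the observed
#' proportion of differences p is computed over gap-free columns, and
#' either returned as-is (`model = "p"`) or Poisson-corrected
#' (`d = -ln(1 - p)`).
#'
#' @param a,b protein strings (unaligned; alignment is internal).
#' @param model "p" or "poisson".
#' @return distance (substitutions per site for "poisson").
#' @export
protein_distance <- function(a, b, model = c("poisson", "p")) {
  model <- match.arg(model)
  aln <- global_align(a, b)
  if (aln$aligned_columns == 0)
    stop("no gap-free columns between sequences")
  p <- 1 - aln$matches / aln$aligned_columns
  if (model == "p") return(p)
  if (p >= 1) stop("saturation: p = 1, Poisson distance undefined")
  -log(1 - p)
}

#' Distance matrix over a protein collection
#'
#' @param proteins `seq_collection`.
#' @inheritParams protein_distance
#' @return symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(proteins, model = c("poisson", "p")) {
  model <- match.arg(model)
  ids <- names(proteins)
  n <- length(ids)
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      d <- protein_distance(proteins[[i]], proteins[[j]], model)
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Neighbor-joining gene tree
#'
#' Saitou-Nei agglomeration (via ape), negative branch lengths clamped to
#' zero with a warning, rooted at the midpoint unless an outgroup taxon is
#' named.
#'
#' @param dm symmetric distance matrix with labels.
#' @param outgroup optional taxon label to root on.
#' @param root logical; FALSE returns the unrooted NJ tree.
#' @return an ape `phylo`.
#' @export
build_nj_tree <- function(dm, outgroup = NULL, root = TRUE) {
  dm <- as.matrix(dm)
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric")
  tr <- ape::nj(as.dist(dm))
  if (any(tr$edge.length < 0)) {
    warning("negative NJ branch length(s) clamped to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  if (!root) return(tr)
  if (!is.null(outgroup)) {
    ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  } else {
    phangorn::midpoint(tr)
  }
}

# p-distance matrix from a character matrix of aligned residues
# (rows = taxa); columns where either row has a gap are dropped pairwise.
.pdist_from_columns <- function(mat, model = "poisson") {
  n <- nrow(mat)
  dm <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      p <- if (any(ok)) mean(mat[i, ok] != mat[j, ok]) else 0
      d <- if (model == "poisson") {
        if (p >= 1) stop("saturation in bootstrap distance") else -log(1 - p)
      } else p
      dm[i, j] <- dm[j, i] <- d
    }
  }
  dm
}

#' Bootstrap branch support for an NJ tree
#'
#' Columns of the alignment are resampled with replacement; an NJ tree is
#' built per replicate and each internal branch of the reference tree is
#' scored by the percentage of replicates containing its bipartition.
#' Seeded and reproducible.
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences (the gene family alignment).
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param model distance model passed to the internal p-distance.
#' @return list `tree` (reference NJ tree, unrooted) and `support`
#'   (percent support per internal node, in `tree$node.label` order).
#' @export
bootstrap_support <- function(alignment, reps = 100, seed = 1,
                              model = "poisson") {
  if (reps <= 0) stop("reps must be >= 1")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) stop("alignment rows differ in length")
  mat <- do.call(rbind, strsplit(unname(alignment), ""))
  rownames(mat) <- names(alignment)
  build <- function(m) build_nj_tree(.pdist_from_columns(m, model),
                                     root = FALSE)
  ref <- build(mat)
  set.seed(seed)
  counts <- ape::boot.phylo(ref, mat, build, B = reps, quiet = TRUE,
                            trees = FALSE)
  support <- 100 * counts / reps
  ref$node.label <- support
  list(tree = ref, support = support)
}
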