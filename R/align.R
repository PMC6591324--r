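#' Pairwise alignment primitives
#'
#' Needleman-Wunsch global and Smith-Waterman local alignment under affine
#' gap penalties, used by candidate screening, duplicate detection and
#' distance computation. The dynamic programming engine is
#' `Biostrings::pairwiseAlignment`; this layer fixes the package's scoring
#' conventions (BLOSUM62, gap open -11 / extend -1, BLAST-style: a gap of
#' length L costs |open| + L*|extend|) and exposes the alignment as a plain
#' record.
#'
#' @param a,b residue strings (non-empty).
#' @param matrix substitution matrix: a matrix, or the name of a matrix
#'   shipped with Biostrings (e.g. "BLOSUM62"), or NULL to use
#'   `match`/`mismatch` scores.
#' @param gap_open,gap_extend gap penalties (negative scores).
#' @param match,mismatch simple scoring used when `matrix` is NULL.
#' @return `gst_alignment`: list with `aligned_a`, `aligned_b`, `score`,
#'   `mode`, `matches`, `mismatches`, `aligned_columns` (gap-free columns)
#'   and `columns` (total alignment length).
#' @examples
#' aln <- global_align("GATTACA", "GATTACA")
#' percent_identity(aln)  # 100
#' @export
global_align <- function(a, b, matrix = "BLOSUM62",
                         gap_open = -11, gap_extend = -1,
                         match = 1, mismatch = -1) {
  .pairwise(a, b, matrix, gap_open, gap_extend, match, mismatch, "global")
}

#' @rdname global_align
#' @export
local_align <- function(a, b, matrix = "BLOSUM62",
                        gap_open = -11, gap_extend = -1,
                        match = 1, mismatch = -1) {
  .pairwise(a, b, matrix, gap_open, gap_extend, match, mismatch, "local")
}

.subst_matrix <- function(matrix, match, mismatch, letters_needed) {
  if (is.matrix(matrix)) return(matrix)
  if (is.character(matrix)) {
    e <- new.env()
    utils::data(list = matrix, package = "Biostrings", envir = e)
    return(get(matrix, envir = e))
  }
  letters_all <- union(LETTERS, letters_needed)
  m <- matrix(mismatch, length(letters_all), length(letters_all),
              dimnames = list(letters_all, letters_all))
  diag(m) <- match
  m
}

.pairwise <- function(a, b, matrix, gap_open, gap_extend, match, mismatch,
                      mode) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence in ", mode, " alignment")
  a <- toupper(a); b <- toupper(b)
  sm <- .subst_matrix(matrix, match, mismatch,
                      unique(strsplit(paste0(a, b), "")[[1]]))
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = mode, substitutionMatrix = sm,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend)
  )
  score <- Biostrings::score(aln)
  if (mode == "local" && score < 0) {
    # Smith-Waterman permits the empty alignment at score 0
    return(structure(list(aligned_a = "", aligned_b = "", score = 0,
                          mode = mode, matches = 0L, mismatches = 0L,
                          aligned_columns = 0L, columns = 0L),
                     class = "gst_alignment"))
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  nmat <- Biostrings::nmatch(aln)
  nmis <- Biostrings::nmismatch(aln)
  structure(list(aligned_a = pa, aligned_b = pb, score = score, mode = mode,
                 matches = as.integer(nmat), mismatches = as.integer(nmis),
                 aligned_columns = as.integer(nmat + nmis),
                 columns = nchar(pa)),
            class = "gst_alignment")
}

#' Karlin-Altschul expectation for an alignment score
#'
#' E = K * m * n * exp(-lambda * S), the BLAST-style expected number of
#' chance alignments at score >= S in a search space of size m*n. Default
#' constants are the published gapped-BLOSUM62 values (lambda = 0.267,
#' K = 0.041), with no edge-effect correction; this approximates the blastp
#' screen the pipeline replaces.
#'
#' @param score alignment score (positive).
#' @param search_space product of query and database lengths (m*n).
#' @param lambda_ka,k_ka Karlin-Altschul parameters.
#' @return the expectation E.
#' @export
evalue <- function(score, search_space, lambda_ka = 0.267, k_ka = 0.041) {
  if (search_space <= 0) stop("search space must be positive")
  stopifnot(lambda_ka > 0, k_ka > 0)
  if (score <= 0) stop("E-value requires a positive score")
  k_ka * search_space * exp(-lambda_ka * score)
}

#' Percent identity of an alignment
#'
#' @param aln a `gst_alignment`.
#' @param denominator "aligned_columns" (gap-free columns; default) or
#'   "shorter_seq" (length of the shorter unaligned sequence).
#' @return identity in \[0, 100\].
#' @export
percent_identity <- function(aln,
                             denominator = c("aligned_columns", "shorter_seq")) {
  stopifnot(inherits(aln, "gst_alignment"))
  denominator <- match.arg(denominator)
  if (aln$columns == 0) stop("percent identity of an empty alignment")
  den <- switch(denominator,
    aligned_columns = aln$aligned_columns,
    shorter_seq = min(nchar(gsub("-", "", aln$aligned_a)),
                      nchar(gsub("-", "", aln$aligned_b))))
  if (den == 0) stop("percent identity undefined: zero-length denominator")
  100 * aln$matches / den
}
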