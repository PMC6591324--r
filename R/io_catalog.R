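#' Read a family catalog table
#'
#' Parses the tab-separated catalog schema used by the packaged pepper GST
#' transcription: one row per gene with name, locus id, CDS coordinates
#' (1-based inclusive), strand, printed gene length, protein length,
#' molecular weight and isoelectric point. The family class is inferred
#' from the gene-name prefix (CaGSTU -> tau, CaGSTF -> phi, CaGSTT -> theta,
#' CaGSTZ -> zeta, CaGSTL -> lambda, CaEF1B -> EF1Bgamma, CaDHAR -> DHAR,
#' CaTCHQD -> TCHQD, CaMGST -> MGST, CaGHR -> GHR) and the chromosome from
#' the locus id.
#'
#' @param path path to a TSV with header
#'   `gene_name locus_id cds_start cds_end strand gene_bp protein_aa mw_kda pi`.
#' @return A `gst_catalog`: data.frame with the columns above plus
#'   `class_label` and `chromosome`.
#' @examples
#' cat85 <- read_catalog_table(gst_table1_path())
#' nrow(cat85)  # 85
#' @export
read_catalog_table <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("catalog validation error: no records in ", path)
  need <- c("gene_name", "locus_id", "cds_start", "cds_end", "strand",
            "gene_bp", "protein_aa", "mw_kda", "pi")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("catalog header missing column(s): ", paste(missing, collapse = ", "))
  num <- function(col, integer = FALSE) {
    v <- suppressWarnings(if (integer) as.integer(df[[col]]) else
      as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(df[[col]]))
    if (length(bad))
      stop("catalog parse error in column '", col, "' at data line ",
           bad[1] + 1L, ": '", df[[col]][bad[1]], "'")
    v
  }
  out <- data.frame(
    gene_name = df$gene_name,
    locus_id = df$locus_id,
    cds_start = num("cds_start", TRUE),
    cds_end = num("cds_end", TRUE),
    strand = df$strand,
    gene_bp = num("gene_bp", TRUE),
    protein_aa = num("protein_aa", TRUE),
    mw_kda = num("mw_kda"),
    pi = num("pi"),
    stringsAsFactors = FALSE
  )
  dup <- out$gene_name[duplicated(out$gene_name)]
  if (length(dup))
    stop("catalog validation error: duplicate gene name(s): ",
         paste(unique(dup), collapse = ", "))
  if (any(out$cds_end < out$cds_start))
    stop("catalog validation error: cds_end < cds_start for ",
         paste(out$gene_name[out$cds_end < out$cds_start], collapse = ", "))
  if (!all(out$strand %in% c("+", "-")))
    stop("catalog validation error: strand must be '+' or '-'")
  out$class_label <- class_from_name(out$gene_name)
  out$chromosome <- vapply(out$locus_id, chromosome_of, integer(1),
                           USE.NAMES = FALSE)
  class(out) <- c("gst_catalog", "data.frame")
  out
}

#' Infer family class labels from gene-name prefixes
#'
#' @param names character vector of gene names (e.g. "CaGSTU29").
#' @return character vector of class labels.
#' @export
class_from_name <- function(names) {
  pref <- names(.class_prefixes)
  out <- rep(NA_character_, length(names))
  # longest prefixes first so CaGSTT does not swallow CaGSTU etc.
  for (p in pref[order(nchar(pref), decreasing = TRUE)]) {
    hit <- is.na(out) & startsWith(names, p)
    out[hit] <- .class_prefixes[[p]]
  }
  if (anyNA(out))
    stop("cannot infer class for gene name(s): ",
         paste(names[is.na(out)], collapse = ", "))
  out
}

#' Path to the packaged pepper GST catalog fixture
#'
#' A verbatim transcription of the published 85-gene pepper GST table
#' (names, locus ids, CDS coordinates, strand, lengths, MW, pI).
#' @return file path.
#' @export
gst_table1_path <- function() {
  system.file("extdata", "pepper_gst_table1.tsv", package = "gstfam")
}
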