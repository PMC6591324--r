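#' Detect duplicate gene pairs
#'
#' Alignment screen for duplicate pairs within a family: every unordered
#' pair of catalog genes whose local-alignment E-value is at most
#' `cfg$evalue_threshold` and whose global percent identity is at least
#' `cfg$identity_threshold_pct` is reported. A gene may appear in several
#' pairs; multiplicity is flagged downstream.
#'
#' @param catalog a `gst_catalog` (or data.frame with `gene_name`,
#'   `chromosome`, `cds_start`, `cds_end`).
#' @param proteins `seq_collection` with one protein per catalog gene.
#' @param cfg a [gst_config()].
#' @return data.frame `gene_a`, `gene_b`, `identity_pct`, `evalue`, `mode`
#'   (tandem/segmental via [classify_pair()]).
#' @export
find_duplicate_pairs <- function(catalog, proteins, cfg = gst_config()) {
  missing <- setdiff(catalog$gene_name, names(proteins))
  if (length(missing))
    stop("missing protein for catalog record(s): ",
         paste(missing, collapse = ", "))
  genes <- catalog$gene_name
  rows <- list()
  if (length(genes) >= 2) {
    for (i in seq_len(length(genes) - 1)) {
      for (j in seq((i + 1), length(genes))) {
        pa <- proteins[[genes[i]]]; pb <- proteins[[genes[j]]]
        loc <- local_align(pa, pb)
        if (loc$score <= 0) next
        e <- evalue(loc$score, search_space = nchar(pa) * nchar(pb))
        if (e > cfg$evalue_threshold) next
        ident <- percent_identity(global_align(pa, pb))
        if (ident < cfg$identity_threshold_pct) next
        rows[[length(rows) + 1]] <- data.frame(
          gene_a = genes[i], gene_b = genes[j],
          identity_pct = ident, evalue = e, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_a = character(), gene_b = character(),
               identity_pct = numeric(), evalue = numeric(),
               stringsAsFactors = FALSE)
  if (nrow(out)) {
    ia <- match(out$gene_a, catalog$gene_name)
    ib <- match(out$gene_b, catalog$gene_name)
    out$mode <- vapply(seq_len(nrow(out)), function(k)
      classify_pair(catalog[ia[k], ], catalog[ib[k], ],
                    window = cfg$tandem_window_bp), character(1))
  } else out$mode <- character()
  out
}

#' Classify a duplicate pair as tandem or segmental
#'
#' Tandem means same chromosome and an inter-gene gap of at most `window`
#' bp (gap between CDS spans, `max(0, larger start - smaller end)`;
#' boundary inclusive). Anything else - including pairs on different
#' chromosomes - is segmental.
#'
#' @param rec_a,rec_b single catalog rows (need `chromosome`, `cds_start`,
#'   `cds_end`).
#' @param window tandem window in bp (default 100 kb).
#' @return "tandem" or "segmental".
#' @export
classify_pair <- function(rec_a, rec_b, window = 100000) {
  if (rec_a$chromosome != rec_b$chromosome) return("segmental")
  if (intergene_distance(rec_a, rec_b) <= window) "tandem" else "segmental"
}

#' @rdname classify_pair
#' @export
intergene_distance <- function(rec_a, rec_b) {
  if (rec_a$cds_start <= rec_b$cds_start)
    max(0, rec_b$cds_start - rec_a$cds_end)
  else
    max(0, rec_a$cds_start - rec_b$cds_end)
}

#' Find genomic gene clusters
#'
#' Single-linkage chaining per chromosome: maximal runs of two or more
#' family genes in which consecutive genes (sorted by start) are separated
#' by at most `window` bp.
#'
#' @param catalog a `gst_catalog`.
#' @param window chaining window in bp.
#' @return data.frame `chromosome`, `members` (comma-joined gene names),
#'   `n_members`, `span_bp`.
#' @export
find_clusters <- function(catalog, window = 100000) {
  out <- list()
  for (chr in sort(unique(catalog$chromosome))) {
    sub <- catalog[catalog$chromosome == chr, ]
    sub <- sub[order(sub$cds_start), ]
    if (nrow(sub) < 2) next
    gap <- pmax(0, sub$cds_start[-1] - sub$cds_end[-nrow(sub)])
    run_id <- cumsum(c(0, gap > window))
    for (r in unique(run_id)) {
      grp <- sub[run_id == r, ]
      if (nrow(grp) < 2) next
      out[[length(out) + 1]] <- data.frame(
        chromosome = chr,
        members = paste(grp$gene_name, collapse = ","),
        n_members = nrow(grp),
        span_bp = max(grp$cds_end) - min(grp$cds_start) + 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chromosome = integer(), members = character(),
               n_members = integer(), span_bp = integer(),
               stringsAsFactors = FALSE)
}

#' Full duplicate-pair report
#'
#' Adds dN/dS ([nei_gojobori()]), divergence time ([divergence_time()])
#' and a selection call (purifying if omega < 1, positive if omega > 1,
#' neutral if omega == 1) to a duplicate-pair table.
#'
#' @param pairs output of [find_duplicate_pairs()].
#' @param cds `seq_collection` of codon sequences named by gene.
#' @param cfg a [gst_config()].
#' @return the pair table with `dn`, `ds`, `omega`, `t_mya`,
#'   `selection_call` columns appended.
#' @export
duplicate_pair_report <- function(pairs, cds, cfg = gst_config()) {
  n <- nrow(pairs)
  pairs$dn <- pairs$ds <- pairs$omega <- pairs$t_mya <- NA_real_
  pairs$selection_call <- NA_character_
  for (k in seq_len(n)) {
    aln <- .codon_align(cds[[pairs$gene_a[k]]], cds[[pairs$gene_b[k]]])
    res <- nei_gojobori(aln[1], aln[2])
    pairs$dn[k] <- res$dn; pairs$ds[k] <- res$ds; pairs$omega[k] <- res$omega
    pairs$t_mya[k] <- divergence_time(res$ds, cfg$lambda_subst)
    pairs$selection_call[k] <-
      if (is.na(res$omega)) NA_character_
      else if (res$omega < 1) "purifying"
      else if (res$omega > 1) "positive" else "neutral"
  }
  pairs
}

# Codon-aware pairwise alignment: align translations globally, then map
# gaps back onto the codon sequences (PAL2NAL-style back-threading).
.codon_align <- function(cds_a, cds_b) {
  prot_a <- .translate_cds(cds_a)
  prot_b <- .translate_cds(cds_b)
  aln <- global_align(prot_a, prot_b)
  thread <- function(aligned_prot, codons) {
    out <- character(nchar(aligned_prot)); i <- 1
    chars <- strsplit(aligned_prot, "")[[1]]
    for (k in seq_along(chars)) {
      if (chars[k] == "-") out[k] <- "---"
      else { out[k] <- codons[i]; i <- i + 1 }
    }
    paste(out, collapse = "")
  }
  c(thread(aln$aligned_a, .split_codons(cds_a)),
    thread(aln$aligned_b, .split_codons(cds_b)))
}

.translate_cds <- function(cds) {
  paste(vapply(.split_codons(cds), .translate_codon, character(1)),
        collapse = "")
}
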