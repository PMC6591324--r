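#' Gene length from CDS coordinates
#'
#' Coordinates are 1-based inclusive, so the span is `end - start + 1`.
#'
#' @param cds_start,cds_end integer coordinates, `cds_end >= cds_start`.
#' @return length in bp.
#' @examples
#' gene_length(211057582, 211057887)  # 306
#' @export
gene_length <- function(cds_start, cds_end) {
  if (any(cds_end < cds_start))
    stop("reversed coordinates: cds_end < cds_start")
  cds_end - cds_start + 1L
}

#' Chromosome from a locus identifier
#'
#' Pepper-style locus ids encode the chromosome as a two-digit field:
#' `Capana09g001740` -> 9; the unanchored bin `00` maps to chromosome 0.
#'
#' @param locus_id locus identifier.
#' @param pattern regex with one capture group for the chromosome field.
#' @return integer chromosome.
#' @export
chromosome_of <- function(locus_id,
                          pattern = "^Capana([0-9]{2})g[0-9]{6}$") {
  m <- regmatches(locus_id, regexec(pattern, locus_id))[[1]]
  if (length(m) < 2)
    stop("locus id does not match pattern '", pattern, "': ", locus_id)
  as.integer(m[2])
}

.check_protein <- function(seq) {
  if (!nzchar(seq)) stop("empty protein sequence")
  seq <- toupper(seq)
  res <- strsplit(seq, "")[[1]]
  bad <- which(!res %in% names(.aa_residue_mass))
  if (length(bad))
    stop("unknown residue '", res[bad[1]], "' at position ", bad[1])
  res
}

#' Molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.0153 Da), in kDa.
#'
#' @param seq protein string over the 20 standard residues.
#' @return molecular weight in kDa.
#' @examples
#' molecular_weight("G")  # 0.0750672 kDa
#' @export
molecular_weight <- function(seq) {
  res <- .check_protein(seq)
  (sum(.aa_residue_mass[res]) + .water_mass) / 1000
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the N-terminus, C-terminus and the
#' ionisable side chains D, E, C, Y, H, K, R using the shipped pKa table.
#'
#' @param seq protein string.
#' @param ph pH value.
#' @param pka pKa table (list with `nterm`, `cterm`, `positive`, `negative`).
#' @return net charge (elementary charges).
#' @export
net_charge <- function(seq, ph, pka = .pka_table) {
  res <- .check_protein(seq)
  pos_pka <- c(pka$nterm, pka$positive[res[res %in% names(pka$positive)]])
  neg_pka <- c(pka$cterm, pka$negative[res[res %in% names(pka$negative)]])
  sum(1 / (1 + 10^(ph - pos_pka))) - sum(1 / (1 + 10^(neg_pka - ph)))
}

#' Theoretical isoelectric point
#'
#' pH at which [net_charge()] crosses zero, found by bisection on \[0, 14\]
#' to |charge| < 1e-4.
#'
#' @inheritParams net_charge
#' @param tol convergence tolerance on |charge|.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka = .pka_table, tol = 1e-4) {
  lo <- 0; hi <- 14
  f <- function(ph) net_charge(seq, ph, pka)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- f(mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Screen a proteome for family candidates
#'
#' Local-alignment stand-in for the blastp screen: every protein whose best
#' local alignment against any query reaches `E <= cfg$evalue_threshold`
#' is reported with its best query and E-value.
#'
#' @param proteome,queries `seq_collection`s of proteins.
#' @param cfg a [gst_config()].
#' @return data.frame `id`, `best_query`, `evalue`, `score`, ordered as in
#'   the proteome.
#' @export
screen_candidates <- function(proteome, queries, cfg = gst_config()) {
  stopifnot(inherits(proteome, "seq_collection"),
            inherits(queries, "seq_collection"))
  if (length(queries) == 0) stop("empty query set")
  if (length(proteome) == 0) stop("empty proteome")
  rows <- lapply(names(proteome), function(id) {
    best <- NULL
    for (q in names(queries)) {
      aln <- local_align(proteome[[id]], queries[[q]])
      if (aln$score <= 0) next
      e <- evalue(aln$score,
                  search_space = nchar(proteome[[id]]) * nchar(queries[[q]]))
      if (is.null(best) || e < best$evalue)
        best <- list(best_query = q, evalue = e, score = aln$score)
    }
    if (!is.null(best) && best$evalue <= cfg$evalue_threshold)
      data.frame(id = id, best_query = best$best_query,
                 evalue = best$evalue, score = best$score,
                 stringsAsFactors = FALSE)
    else NULL
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), best_query = character(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  out
}

#' Assign a family class by nearest labeled reference
#'
#' Deterministic surrogate for a conserved-domain database lookup: the
#' member gets the class of the reference with the highest global-alignment
#' score; ties break by higher identity, then lexicographic reference id.
#'
#' @param protein protein string.
#' @param references `seq_collection` of labeled references.
#' @param ref_classes character vector of class labels, parallel to
#'   `references` (default: taken from reference names' prefixes).
#' @return list `class_label`, `best_reference`, `score`, `identity_pct`.
#' @export
classify_member <- function(protein, references, ref_classes = NULL) {
  stopifnot(inherits(references, "seq_collection"))
  if (length(references) == 0) stop("no references to classify against")
  if (is.null(ref_classes)) ref_classes <- class_from_name(names(references))
  stopifnot(length(ref_classes) == length(references))
  scores <- numeric(length(references))
  idents <- numeric(length(references))
  for (i in seq_along(references)) {
    aln <- global_align(protein, references[[i]])
    scores[i] <- aln$score
    idents[i] <- percent_identity(aln)
  }
  ord <- order(-scores, -idents, names(references))
  best <- ord[1]
  tied <- which(scores == scores[best] & idents == idents[best])
  if (length(unique(ref_classes[tied])) > 1)
    warning("class tie between references ",
            paste(names(references)[tied], collapse = ", "),
            "; deterministic tie-break applied")
  list(class_label = ref_classes[best],
       best_reference = names(references)[best],
       score = scores[best], identity_pct = idents[best])
}

#' Summarise a family catalog
#'
#' Counts per class and chromosome (with percentages), and min/mean/max of
#' gene length, protein length, molecular weight and pI with the records
#' attaining the extremes.
#'
#' @param catalog a `gst_catalog`.
#' @return list with `n`, `class_counts`, `chromosome_counts`,
#'   `chromosome_pct`, and a `stats` data.frame.
#' @export
summarize_family <- function(catalog) {
  stopifnot(inherits(catalog, "data.frame"), nrow(catalog) >= 1)
  class_counts <- table(factor(catalog$class_label, levels = .class_levels))
  chrom_counts <- table(catalog$chromosome)
  span <- gene_length(catalog$cds_start, catalog$cds_end)
  one <- function(name, x) {
    i_min <- which.min(x); i_max <- which.max(x)
    data.frame(statistic = name, min = min(x), mean = mean(x), max = max(x),
               min_record = catalog$gene_name[i_min],
               max_record = catalog$gene_name[i_max],
               stringsAsFactors = FALSE)
  }
  stats_df <- rbind(one("gene_span_bp", span),
                    one("gene_bp", catalog$gene_bp),
                    one("protein_aa", catalog$protein_aa),
                    one("mw_kda", catalog$mw_kda),
                    one("pi", catalog$pi))
  list(n = nrow(catalog),
       class_counts = class_counts,
       chromosome_counts = chrom_counts,
       chromosome_pct = round(100 * chrom_counts / nrow(catalog), 1),
       stats = stats_df)
}

#' Compare two exon/intron structures
#'
#' Orientation is from `a` to `b`: more exons in `b` is an intron gain.
#'
#' @param a,b lists with an `exons` element: two-column matrix or
#'   data.frame of (start, end), non-overlapping and sorted.
#' @return list `exon_delta`, `intron_delta`,
#'   `classification` in `same_count` / `intron_gain` / `intron_loss`.
#' @export
compare_structures <- function(a, b) {
  n_ex <- function(s) {
    ex <- as.matrix(s$exons)
    if (nrow(ex) == 0) stop("empty exon list")
    if (any(ex[, 2] < ex[, 1])) stop("exon end < start")
    if (is.unsorted(ex[, 1])) stop("exons must be sorted by start")
    if (nrow(ex) > 1 && any(ex[-1, 1] <= ex[-nrow(ex), 2]))
      stop("exons overlap")
    nrow(ex)
  }
  da <- n_ex(a); db <- n_ex(b)
  delta <- db - da
  list(exon_delta = delta, intron_delta = delta,
       classification = if (delta > 0) "intron_gain"
                        else if (delta < 0) "intron_loss"
                        else "same_count")
}
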