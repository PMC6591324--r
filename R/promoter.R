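#' Extract the upstream (promoter) window of a gene
#'
#' Returns the `length` bases 5' of the CDS start, strand-aware: for a
#' minus-strand gene the window lies 3' of the CDS end on the reference
#' and is reverse-complemented. Windows running off the contig edge are
#' clipped with a warning.
#'
#' @param genome `seq_collection` (dna) of contigs.
#' @param features `gst_features` table with gene rows (`id`, `seqid`,
#'   `start`, `end`, `strand`).
#' @param gene_id gene feature id.
#' @param length window length in bp (> 0), default 1000.
#' @return upstream sequence (5'->3' relative to the gene).
#' @export
extract_upstream <- function(genome, features, gene_id, length = 1000) {
  if (length <= 0) stop("zero-length upstream window")
  g <- features[features$type == "gene" & features$id == gene_id, ]
  if (nrow(g) == 0) stop("gene not found in features: ", gene_id)
  g <- g[1, ]
  contig <- genome[[g$seqid]]
  if (is.null(contig)) stop("contig not found in genome: ", g$seqid)
  clen <- nchar(contig)
  if (g$strand == "+") {
    from <- g$start - length
    to <- g$start - 1
    if (from < 1) {
      warning("upstream window clipped at contig start for ", gene_id)
      from <- 1
    }
    if (to < from) return("")
    substr(contig, from, to)
  } else {
    from <- g$end + 1
    to <- g$end + length
    if (to > clen) {
      warning("upstream window clipped at contig end for ", gene_id)
      to <- clen
    }
    if (to < from) return("")
    revcomp(substr(contig, from, to))
  }
}

.iupac_match <- function(pattern_chars, window_chars) {
  all(vapply(seq_along(pattern_chars), function(i)
    window_chars[i] %in% .iupac_map[[pattern_chars[i]]], logical(1)))
}

.iupac_class <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                  H = "[ACT]", V = "[ACG]", N = "[ACGT]")

.iupac_regex <- function(consensus) {
  paste(.iupac_class[strsplit(consensus, "")[[1]]], collapse = "")
}

# reverse complement for IUPAC consensus strings (cheap, no XString)
.revcomp_chr <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' Scan a sequence for cis-element consensus matches
#'
#' Every position where an element's IUPAC consensus matches is reported
#' (overlapping matches allowed); with `both_strands` the reverse
#' complement of the consensus is scanned too, reported on the "-" strand
#' at the position of the + -strand locus. IUPAC ambiguity codes in the
#' consensus match their base sets.
#'
#' @param seq DNA string (the promoter window).
#' @param elements cis-element catalog (see [read_cis_elements()]).
#' @param both_strands scan the minus strand as well (default TRUE).
#' @param overlapping count overlapping matches individually (default TRUE).
#' @return data.frame `element`, `position` (1-based), `strand`, ordered
#'   by position then strand.
#' @export
scan_elements <- function(seq, elements = default_cis_elements(),
                          both_strands = TRUE, overlapping = TRUE) {
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(elements$consensus))
  if (any(bad))
    stop("illegal IUPAC letter in element(s): ",
         paste(elements$name[bad], collapse = ", "))
  seq <- toupper(seq)
  hits <- list()
  scan_one <- function(consensus, strand, name) {
    if (nchar(consensus) > nchar(seq)) return(NULL)
    # zero-width lookahead reports overlapping matches too
    m <- gregexpr(paste0("(?=", .iupac_regex(consensus), ")"), seq,
                  perl = TRUE)[[1]]
    pos <- if (m[1] == -1L) integer(0) else as.integer(m)
    if (!overlapping && length(pos) > 1) {
      keep <- pos[1]; last_end <- pos[1] + nchar(consensus) - 1
      for (p in pos[-1]) if (p > last_end) {
        keep <- c(keep, p); last_end <- p + nchar(consensus) - 1
      }
      pos <- keep
    }
    if (length(pos) == 0) return(NULL)
    data.frame(element = name, position = pos, strand = strand,
               stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(elements))) {
    el <- elements[i, ]
    hits[[length(hits) + 1]] <- scan_one(el$consensus, "+", el$name)
    if (both_strands)
      hits[[length(hits) + 1]] <- scan_one(.revcomp_chr(el$consensus), "-",
                                           el$name)
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    return(data.frame(element = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  out[order(out$position, out$strand, out$element), , drop = FALSE]
}

#' Cis-element count matrix over gene promoters
#'
#' @param upstreams named character vector of promoter sequences (one per
#'   gene).
#' @param elements cis-element catalog.
#' @param ... passed to [scan_elements()].
#' @return list `counts` (genes x elements integer matrix), `row_totals`,
#'   `col_totals`, `category_totals`.
#' @export
element_count_matrix <- function(upstreams, elements = default_cis_elements(),
                                 ...) {
  if (length(upstreams) < 1) stop("need at least one promoter")
  counts <- matrix(0L, length(upstreams), nrow(elements),
                   dimnames = list(names(upstreams), elements$name))
  for (g in names(upstreams)) {
    h <- scan_elements(upstreams[[g]], elements, ...)
    if (nrow(h)) {
      tab <- table(h$element)
      counts[g, names(tab)] <- as.integer(tab)
    }
  }
  cat_tot <- tapply(colSums(counts), elements$category, sum)
  list(counts = counts,
       row_totals = rowSums(counts),
       col_totals = colSums(counts),
       category_totals = cat_tot)
}
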