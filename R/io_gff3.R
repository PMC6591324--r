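#' GFF3 gene-model I/O
#'
#' Reads a GFF3 file into a flat feature table (one row per gene / mRNA /
#' exon / CDS feature, 1-based inclusive coordinates) with the parent
#' hierarchy resolved through `Parent` attributes, and writes it back.
#' Parsing and serialisation are delegated to rtracklayer; this layer
#' validates the hierarchy: every mRNA must name a known gene parent and
#' every exon/CDS a known mRNA parent, and children must lie within their
#' parent's span.
#'
#' @param path GFF3 file path.
#' @return `gst_features`: data.frame with columns `seqid`, `source`,
#'   `type`, `start`, `end`, `strand`, `phase`, `id`, `parent`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "mRNA", "exon", "CDS")
  gr <- gr[keep]
  parent <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  id <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  fs <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    source = if (!is.null(gr$source)) as.character(gr$source) else "gstfam",
    type = as.character(gr$type),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    phase = if (!is.null(gr$phase)) as.integer(gr$phase) else NA_integer_,
    id = id,
    parent = parent,
    stringsAsFactors = FALSE
  )
  validate_features(fs)
}

#' @rdname read_gff3
#' @param fs a `gst_features` table.
#' @export
write_gff3 <- function(fs, path) {
  fs <- validate_features(fs)
  gr <- GenomicRanges::GRanges(
    seqnames = fs$seqid,
    ranges = IRanges::IRanges(fs$start, fs$end),
    strand = fs$strand
  )
  gr$source <- fs$source
  gr$type <- fs$type
  gr$ID <- fs$id
  gr$Parent <- ifelse(is.na(fs$parent), NA_character_, fs$parent)
  gr$phase <- fs$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Validate a feature table
#'
#' @param fs data.frame in the `read_gff3` schema.
#' @return the validated table with class `gst_features`.
#' @export
validate_features <- function(fs) {
  stopifnot(is.data.frame(fs))
  if (any(fs$end < fs$start))
    stop("feature validation error: end < start for feature(s) ",
         paste(stats::na.omit(fs$id[fs$end < fs$start]), collapse = ", "))
  if (!all(fs$type %in% c("gene", "mRNA", "exon", "CDS")))
    stop("feature validation error: unknown feature type(s): ",
         paste(setdiff(fs$type, c("gene", "mRNA", "exon", "CDS")), collapse = ", "))
  genes <- fs[fs$type == "gene", ]
  mrnas <- fs[fs$type == "mRNA", ]
  kids <- fs[fs$type %in% c("exon", "CDS"), ]
  if (nrow(mrnas) && !all(mrnas$parent %in% genes$id))
    stop("mRNA with unknown gene Parent: ",
         paste(mrnas$id[!mrnas$parent %in% genes$id], collapse = ", "))
  if (nrow(kids) && !all(kids$parent %in% mrnas$id))
    stop("exon/CDS with unknown mRNA Parent: ",
         paste(kids$parent[!kids$parent %in% mrnas$id], collapse = ", "))
  # children within the parent span
  check_span <- function(child, parents) {
    i <- match(child$parent, parents$id)
    bad <- child$start < parents$start[i] | child$end > parents$end[i]
    if (any(bad))
      stop("feature validation error: child outside parent span: ",
           paste(child$parent[bad], collapse = ", "))
  }
  if (nrow(mrnas)) check_span(mrnas, genes)
  if (nrow(kids)) check_span(kids, mrnas)
  class(fs) <- c("gst_features", "data.frame")
  fs
}
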