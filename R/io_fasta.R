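#' Sequence collections and FASTA I/O
#'
#' A `seq_collection` is a named character vector of uppercase residue
#' strings with an `alphabet` attribute ("dna" or "protein"). FASTA parsing
#' is delegated to Biostrings; this layer enforces the collection contract:
#' unique ids, declared alphabet, uppercase normalisation.
#'
#' @param sequences named character vector (names = ids).
#' @param alphabet "dna" or "protein".
#' @param descriptions optional character vector of descriptions.
#' @return object of class `seq_collection`.
#' @export
seq_collection <- function(sequences, alphabet = c("protein", "dna"),
                           descriptions = NULL) {
  alphabet <- match.arg(alphabet)
  if (length(sequences) &&
      (is.null(names(sequences)) || any(!nzchar(names(sequences)))))
    stop("every sequence needs an id (names attribute)")
  if (length(sequences) == 0) names(sequences) <- character(0)
  dup <- names(sequences)[duplicated(names(sequences))]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  sequences <- toupper(sequences)
  ok_chars <- if (alphabet == "dna")
    "^[ACGTRYSWKMBDHVN]*$" else "^[ACDEFGHIKLMNPQRSTVWYXBZJU*]*$"
  bad <- !grepl(ok_chars, sequences)
  if (any(bad))
    stop("illegal residue for alphabet '", alphabet, "' in record(s): ",
         paste(names(sequences)[bad], collapse = ", "))
  structure(sequences, alphabet = alphabet,
            descriptions = descriptions, class = "seq_collection")
}

#' @rdname seq_collection
#' @param path FASTA file path.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  desc <- sub("^\\S+\\s*", "", names(ss))
  seq_collection(stats::setNames(as.character(ss), ids), alphabet,
                 descriptions = desc)
}

#' @rdname seq_collection
#' @param coll a `seq_collection`.
#' @export
write_fasta <- function(coll, path) {
  stopifnot(inherits(coll, "seq_collection"))
  ss <- Biostrings::BStringSet(unclass(coll)[seq_along(coll)])
  names(ss) <- names(coll)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Reverse complement of a DNA string
#'
#' IUPAC-aware, via Biostrings.
#' @param x single DNA string.
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
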