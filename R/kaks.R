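#' Synonymous and nonsynonymous site counts (Nei-Gojobori)
#'
#' For each codon position, each of the three possible single-nucleotide
#' changes contributes 1/3 of a site: to S if the change is synonymous,
#' to N if it changes the amino acid. Changes creating a stop codon are
#' excluded from the site count altogether, so S + N = 3 * (codons) minus
#' 1/3 per excluded stop path.
#'
#' @param seq in-frame CDS string (length divisible by 3, no internal
#'   stop codons; a terminal stop codon is dropped).
#' @return named numeric `c(S = ..., N = ...)`.
#' @examples
#' count_sites("TTT")  # S = 1/3, N = 8/3
#' count_sites("ATG")  # S = 0,   N = 3
#' @export
count_sites <- function(seq) {
  codons <- .split_codons(seq)
  s <- 0; n <- 0
  for (cod in codons) {
    cnt <- .codon_sites(cod)
    s <- s + cnt[1]; n <- n + cnt[2]
  }
  c(S = s, N = n)
}

.genetic_code <- function() Biostrings::GENETIC_CODE

.translate_codon <- function(codon) {
  aa <- .genetic_code()[[codon]]
  if (is.null(aa)) stop("unknown codon: ", codon)
  aa
}

.split_codons <- function(seq) {
  seq <- toupper(gsub("\\s", "", seq))
  if (!nzchar(seq)) stop("empty CDS")
  if (nchar(seq) %% 3 != 0)
    stop("CDS length ", nchar(seq), " is not a multiple of 3")
  codons <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  aas <- vapply(codons, .translate_codon, character(1))
  # drop a terminal stop, reject internal ones
  if (aas[length(aas)] == "*") {
    codons <- codons[-length(codons)]
    aas <- aas[-length(aas)]
  }
  if (any(aas == "*"))
    stop("internal stop codon at codon ", which(aas == "*")[1])
  codons
}

.nt <- c("A", "C", "G", "T")

.codon_sites <- function(codon) {
  aa <- .translate_codon(codon)
  s <- 0; n <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(.nt, chars[pos])) {
      mut <- chars; mut[pos] <- alt
      maa <- .translate_codon(paste(mut, collapse = ""))
      if (maa == "*") next            # stop paths excluded from the sites
      if (maa == aa) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s, n)
}

# Average synonymous/nonsynonymous difference counts between two codons
# over all minimal mutational pathways, excluding pathways that pass
# through a stop codon (equal weighting of the remaining pathways). If
# every pathway is blocked by a stop, all pathways are used as a fallback.
.codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]; b <- strsplit(cb, "")[[1]]
  diff_pos <- which(a != b)
  nd <- length(diff_pos)
  if (nd == 0) return(c(0, 0))
  perms <- .permutations(diff_pos)
  count_path <- function(order, allow_stop) {
    cur <- a; sd <- 0; ndv <- 0
    for (p in order) {
      nxt <- cur; nxt[p] <- b[p]
      aa1 <- .translate_codon(paste(cur, collapse = ""))
      aa2 <- .translate_codon(paste(nxt, collapse = ""))
      if (aa2 == "*" && !identical(nxt, b) && !allow_stop) return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else ndv <- ndv + 1
      cur <- nxt
    }
    c(sd, ndv)
  }
  paths <- Filter(Negate(is.null), lapply(perms, count_path, allow_stop = FALSE))
  if (length(paths) == 0)
    paths <- lapply(perms, count_path, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

.permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in .permutations(x[-i]))
      out <- c(out, list(c(x[i], rest)))
  out
}

#' Jukes-Cantor distance correction
#'
#' d = -(3/4) * ln(1 - 4p/3).
#' @param p observed proportion of differences per site, p < 3/4.
#' @return corrected substitutions per site.
#' @export
jukes_cantor <- function(p) {
  if (any(p < 0)) stop("negative proportion")
  if (any(p >= 0.75))
    stop("saturation: p >= 3/4, Jukes-Cantor distance undefined")
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori dN/dS between two coding sequences
#'
#' Proportions of synonymous (pS = Sd / mean S) and nonsynonymous
#' (pN = Nd / mean N) differences are counted per Nei-Gojobori (equal
#' weighting over all minimal mutational pathways between differing codons,
#' stop-codon pathways excluded) and Jukes-Cantor corrected. Site counts S
#' and N are averaged over the two sequences.
#'
#' @param cds_a,cds_b codon-aligned CDS strings of equal length; columns
#'   where either sequence has a gap are stripped codon-wise.
#' @return list `dn`, `ds`, `omega` (NA when ds == 0), plus the
#'   intermediate counts `Sd`, `Nd`, `S`, `N`, `pS`, `pN`.
#' @export
nei_gojobori <- function(cds_a, cds_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  if (nchar(cds_a) != nchar(cds_b))
    stop("codon-aligned sequences must have equal length")
  if (nchar(cds_a) %% 3 != 0) stop("alignment length not a multiple of 3")
  # strip codon pairs containing a gap in either sequence
  ca <- substring(cds_a, seq(1, nchar(cds_a), 3), seq(3, nchar(cds_a), 3))
  cb <- substring(cds_b, seq(1, nchar(cds_b), 3), seq(3, nchar(cds_b), 3))
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0) stop("no ungapped codons in alignment")
  # drop a shared terminal stop codon
  n_all <- length(ca)
  if (.translate_codon(ca[n_all]) == "*" && .translate_codon(cb[n_all]) == "*") {
    ca <- ca[-n_all]; cb <- cb[-n_all]
  }
  sites_a <- count_sites(paste(ca, collapse = ""))
  sites_b <- count_sites(paste(cb, collapse = ""))
  sd <- 0; ndv <- 0
  for (i in seq_along(ca)) {
    d <- .codon_diffs(ca[i], cb[i])
    sd <- sd + d[1]; ndv <- ndv + d[2]
  }
  s_bar <- (sites_a["S"] + sites_b["S"]) / 2
  n_bar <- (sites_a["N"] + sites_b["N"]) / 2
  ps <- as.numeric(sd / s_bar)
  pn <- as.numeric(ndv / n_bar)
  ds <- jukes_cantor(ps)
  dn <- jukes_cantor(pn)
  list(dn = dn, ds = ds,
       omega = if (ds == 0) NA_real_ else dn / ds,
       Sd = sd, Nd = ndv,
       S = as.numeric(s_bar), N = as.numeric(n_bar), pS = ps, pN = pn)
}

#' Divergence time from synonymous divergence
#'
#' T = dS / (2 * lambda), reported in million years.
#'
#' @param ds synonymous substitutions per site (>= 0).
#' @param lambda_subst clock rate in substitutions per site per year
#'   (default 1.5e-8, the dicot rate).
#' @return time in Mya.
#' @examples
#' divergence_time(0.03)  # 1 Mya
#' @export
divergence_time <- function(ds, lambda_subst = 1.5e-8) {
  if (any(ds < 0)) stop("negative ds")
  stopifnot(lambda_subst > 0)
  ds / (2 * lambda_subst) / 1e6
}
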