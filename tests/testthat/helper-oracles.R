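# Independent brute-force oracles. These deliberately share no code with
# the implementation paths they check.

# --- alignment: enumerate every global alignment of two short sequences
# under linear gap costs (gap_open == gap_extend), return the optimal score
oracle_global_score <- function(a, b, score_fun, gap) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0)
      best <- max(best, rec(i - 1, j - 1) + score_fun(a[i], b[j]))
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(length(a), length(b))
}

# --- Nei-Gojobori per-codon site counts by direct enumeration of the nine
# single-nucleotide changes
oracle_codon_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  nts <- c("A", "C", "G", "T")
  s <- 0; n <- 0
  for (p in 1:3) {
    for (alt in setdiff(nts, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- alt
      maa <- gc[[mut]]
      if (maa == "*") next
      if (maa == aa) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(S = s, N = n)
}

# --- pathway enumeration between two codons (equal weighting, stop paths
# excluded, fallback to all paths when every pathway is blocked)
oracle_codon_path <- function(ca, cb) {
  gc <- Biostrings::GENETIC_CODE
  d <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
  if (length(d) == 0) return(c(0, 0))
  perms <- if (length(d) == 1) list(d) else {
    if (length(d) == 2) list(d, rev(d)) else {
      out <- list()
      for (i in 1:3) for (j in setdiff(1:3, i))
        out <- c(out, list(d[c(i, j, setdiff(1:3, c(i, j)))]))
      out
    }
  }
  walk <- function(ord, allow_stop) {
    cur <- ca; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (gc[[nxt]] == "*" && nxt != cb && !allow_stop) return(NULL)
      if (gc[[cur]] == gc[[nxt]]) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- Filter(Negate(is.null), lapply(perms, walk, allow_stop = FALSE))
  if (!length(paths)) paths <- lapply(perms, walk, allow_stop = TRUE)
  Reduce(`+`, paths) / length(paths)
}

# --- pI by exhaustive pH grid search on the same charge model
oracle_pi_grid <- function(seq, step = 1e-5) {
  grid <- seq(0, 14, by = step)
  q <- vapply(grid, function(ph) net_charge(seq, ph), numeric(1))
  grid[which.min(abs(q))]
}

# --- O(n^3) agglomerative clustering (average linkage, Manhattan) from
# first principles; returns the sorted merge heights
oracle_average_linkage_heights <- function(m) {
  clusters <- lapply(seq_len(nrow(m)), identity)
  manhattan <- function(i, j) sum(abs(m[i, ] - m[j, ]))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        dd <- mean(outer(clusters[[i]], clusters[[j]], Vectorize(manhattan)))
        if (dd < best_d) { best_d <- dd; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# --- sliding-window IUPAC scanner, character by character
oracle_scan <- function(seq, consensus, strand = "+") {
  iupac <- list(A = "A", C = "C", G = "G", T = "T",
                R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                B = c("C", "G", "T"), D = c("A", "G", "T"),
                H = c("A", "C", "T"), V = c("A", "C", "G"),
                N = c("A", "C", "G", "T"))
  rc <- function(x) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
              S = "S", W = "W", K = "M", M = "K", B = "V", V = "B",
              D = "H", H = "D", N = "N")
    paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
  }
  if (strand == "-") consensus <- rc(consensus)
  sq <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(toupper(consensus), "")[[1]]
  hits <- integer(0)
  if (length(pat) <= length(sq)) {
    for (start in seq_len(length(sq) - length(pat) + 1)) {
      ok <- TRUE
      for (k in seq_along(pat)) {
        if (!sq[start + k - 1] %in% iupac[[pat[k]]]) { ok <- FALSE; break }
      }
      if (ok) hits <- c(hits, start)
    }
  }
  hits
}

# temp-file Newick reader
tree_from_text <- function(txt) {
  tf <- withr::local_tempfile(fileext = ".nwk",
                              .local_envir = parent.frame())
  writeLines(txt, tf)
  read_newick(tf)
}
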