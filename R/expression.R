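#' Read an expression matrix TSV
#'
#' Genes in rows (first column = gene id), conditions in columns.
#'
#' @param path TSV path.
#' @return numeric matrix with gene rownames.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance values")
  m
}

#' Fold change relative to a control column
#'
#' Per gene and condition, `(x + c) / (x0 + c)` with pseudocount `c`
#' guarding zero controls; the control column itself maps to 1. With
#' `log2 = TRUE` values are log2-transformed for display (control = 0).
#'
#' @param m non-negative expression matrix.
#' @param control control column name or index (e.g. the 0-h timepoint).
#' @param pseudocount added to numerator and denominator (default 1).
#' @param log2 return log2 ratios.
#' @return matrix of (log2) fold changes.
#' @export
fold_change <- function(m, control, pseudocount = 1, log2 = FALSE) {
  if (is.character(control) && !control %in% colnames(m))
    stop("control column '", control, "' not present")
  x0 <- m[, control]
  fc <- (m + pseudocount) / (x0 + pseudocount)
  if (log2) fc <- log2(fc)
  fc
}

#' Row-scale a matrix to 0-100 percent
#'
#' Per gene, `(x - min) / (max - min) * 100` (the heatmap convention where
#' 100 is the gene's maximum and 0 its minimum). A constant row becomes
#' all zeros with a warning.
#'
#' @param m numeric matrix with >= 1 column.
#' @return matrix in \[0, 100\].
#' @export
row_scale_percent <- function(m) {
  stopifnot(ncol(m) >= 1)
  rmin <- apply(m, 1, min)
  rmax <- apply(m, 1, max)
  flat <- rmax == rmin
  if (any(flat))
    warning("constant row(s) scaled to all-zero: ",
            paste(rownames(m)[flat], collapse = ", "))
  denom <- ifelse(flat, 1, rmax - rmin)
  out <- (m - rmin) / denom * 100
  out[flat, ] <- 0
  out
}

#' Assign low/medium/high expression tiers
#'
#' Genes are ranked by mean log abundance and split at tertiles;
#' ties resolve deterministically by gene-id order. If all means are
#' equal, every gene is assigned "low" with a warning.
#'
#' @param m non-negative expression matrix (>= 3 genes).
#' @param pseudocount added before the log.
#' @return named factor with levels low/medium/high.
#' @export
assign_tier <- function(m, pseudocount = 1) {
  stopifnot(nrow(m) >= 3)
  means <- rowMeans(log(m + pseudocount))
  if (length(unique(means)) == 1) {
    warning("all gene means equal; assigning every gene to 'low'")
    return(stats::setNames(factor(rep("low", nrow(m)),
                                  levels = c("low", "medium", "high")),
                           rownames(m)))
  }
  ord <- order(means, rownames(m))
  n <- nrow(m)
  cut1 <- floor(n / 3); cut2 <- floor(2 * n / 3)
  tier <- character(n)
  tier[ord[seq_len(cut1)]] <- "low"
  tier[ord[seq(cut1 + 1, cut2)]] <- "medium"
  tier[ord[seq(cut2 + 1, n)]] <- "high"
  stats::setNames(factor(tier, levels = c("low", "medium", "high")),
                  rownames(m))
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering with the Manhattan (city-block) metric,
#' `d(g,h) = sum_i |g_i - h_i|`, and average linkage by default (the
#' MeV-style heatmap configuration). Wraps `stats::hclust`.
#'
#' @param m expression matrix (genes in rows, >= 2).
#' @param metric distance metric (default "manhattan").
#' @param linkage "average", "single" or "complete".
#' @return list `hclust` (the stats::hclust object), `order` (leaf order,
#'   gene ids), `heights` (merge heights), `metric`, `linkage`.
#' @export
hier_cluster <- function(m, metric = "manhattan",
                         linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  if (nrow(m) < 2) stop("clustering needs at least 2 genes")
  d <- stats::dist(m, method = metric)
  hc <- stats::hclust(d, method = linkage)
  list(hclust = hc, order = rownames(m)[hc$order], heights = hc$height,
       metric = metric, linkage = linkage)
}
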