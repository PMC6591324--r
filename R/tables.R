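# Physical constants and lookup tables shared across modules.

# Average (isotope-weighted) residue masses in Da, i.e. amino-acid mass
# minus one water; summing residues and adding one water gives peptide MW.
.aa_residue_mass <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.water_mass <- 18.0153

# pKa values used by the Henderson-Hasselbalch net-charge model.
# Terminal groups plus the ionisable side chains D,E,C,Y,H,K,R.
.pka_table <- list(
  nterm = 7.5, cterm = 3.55,
  positive = c(H = 5.98, K = 10.0, R = 12.0),
  negative = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
)

# IUPAC nucleotide ambiguity codes -> the set of bases each matches.
.iupac_map <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Gene-name prefix -> family class label.
.class_prefixes <- c(
  CaGSTU = "tau", CaGSTF = "phi", CaGSTT = "theta", CaGSTZ = "zeta",
  CaGSTL = "lambda", CaEF1B = "EF1Bgamma", CaDHAR = "DHAR",
  CaTCHQD = "TCHQD", CaMGST = "MGST", CaGHR = "GHR"
)

.class_levels <- c("tau", "phi", "theta", "zeta", "lambda", "EF1Bgamma",
                   "DHAR", "TCHQD", "MGST", "GHR")

#' Default cis-regulatory element catalog
#'
#' One IUPAC consensus per named element, grouped into hormone-responsive,
#' stress/defense-responsive, and enhancer categories. Consensi follow
#' commonly cited PlantCARE entries; server-internal patterns differ per
#' entry version, so per-element counts on real promoters are a
#' documentation comparison, not a test gate.
#'
#' @return data.frame with columns `name`, `consensus`, `category`.
#' @export
default_cis_elements <- function() {
  path <- system.file("extdata", "cis_elements.tsv", package = "gstfam")
  read_cis_elements(path)
}

#' Read a cis-element catalog TSV
#'
#' @param path TSV with columns name, consensus, category.
#' @return data.frame validated against the IUPAC DNA alphabet.
#' @export
read_cis_elements <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "consensus", "category")
  if (!all(need %in% names(df)))
    stop("cis-element catalog must have columns: ", paste(need, collapse = ", "))
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", toupper(df$consensus))
  if (any(bad))
    stop("illegal IUPAC letter in consensus for element(s): ",
         paste(df$name[bad], collapse = ", "))
  df$consensus <- toupper(df$consensus)
  df
}
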