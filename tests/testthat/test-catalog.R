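test_that("gene_length follows the 1-based inclusive convention", {
  expect_equal(gene_length(211057582, 211057887), 306)
  expect_equal(gene_length(116162258, 116176687), 14430)
  expect_equal(gene_length(5, 5), 1)
  expect_error(gene_length(10, 9), "reversed")
})

test_that("printed gene lengths agree with coordinate spans (with the two
           known transcription exceptions)", {
  cat85 <- read_catalog_table(gst_table1_path())
  span <- gene_length(cat85$cds_start, cat85$cds_end)
  disagree <- cat85$gene_name[span != cat85$gene_bp]
  # the published table itself prints 630 for CaGSTU28 (span 1775) and
  # 1223 for CaGSTU31 (span 1283); all other 83 rows agree
  expect_setequal(disagree, c("CaGSTU28", "CaGSTU31"))
})

test_that("chromosome_of parses the locus pattern", {
  expect_equal(chromosome_of("Capana09g001740"), 9)
  expect_equal(chromosome_of("Capana00g001895"), 0)
  expect_error(chromosome_of("badid"), "pattern")
  cat85 <- read_catalog_table(gst_table1_path())
  expect_equal(sum(table(cat85$chromosome)), 85)
})

test_that("molecular weight is the residue-mass sum plus one water", {
  expect_equal(molecular_weight("G"), (57.0519 + 18.0153) / 1000)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GXG"), "unknown residue")
  # additivity: MW(a ++ b) = MW(a) + MW(b) - water
  set.seed(3)
  aas <- names(gstfam:::.aa_residue_mass)
  for (i in 1:6) {
    a <- paste(sample(aas, sample(1:30, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(1:30, 1), TRUE), collapse = "")
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 0.0180153,
                 tolerance = 1e-10)
  }
})

test_that("isoelectric point matches a brute-force pH grid search", {
  for (seq in c("K", "DDDD", "KKKK", "MKVDEHRC", "ACDEFGHIKLMNPQRSTVWY")) {
    pi_b <- isoelectric_point(seq)
    expect_lt(abs(net_charge(seq, pi_b)), 1e-4)
    expect_lt(abs(pi_b - oracle_pi_grid(seq, step = 1e-4)), 1e-3)
  }
  expect_gt(isoelectric_point("KKKKKK"), isoelectric_point("DDDDDD"))
})

test_that("screen_candidates recovers planted family members", {
  sim <- get_sim()
  queries <- seq_collection(c(q1 = sim$proteins[[1]]), "protein")
  hits <- screen_candidates(sim$proteins, queries)
  # the query itself is in the proteome and must be recovered
  expect_true(sim$catalog$gene_name[1] %in% hits$id)
  expect_true(all(hits$evalue <= 1e-10))
  # an unrelated decoy protein is not picked up
  set.seed(1)
  decoy <- paste(sample(names(gstfam:::.aa_residue_mass), 300, TRUE),
                 collapse = "")
  prot2 <- seq_collection(c(unclass(sim$proteins)[1:4], decoy1 = decoy),
                          "protein")
  hits2 <- screen_candidates(prot2, queries)
  expect_false("decoy1" %in% hits2$id)
  # zero threshold admits nothing
  expect_equal(nrow(screen_candidates(sim$proteins, queries,
                                      gst_config(evalue_threshold = 0))), 0)
  expect_error(screen_candidates(sim$proteins,
                                 seq_collection(character(), "protein")),
               "empty query")
})

test_that("classify_member assigns by nearest reference deterministically", {
  sim <- get_sim()
  refs <- seq_collection(
    stats::setNames(unclass(sim$proteins)[c(1, 13)],
                    c("CaGSTU1", "CaGSTF1")),
    "protein")
  classes <- c("tau", "phi")
  self <- classify_member(refs[["CaGSTU1"]], refs, classes)
  expect_equal(self$class_label, "tau")
  expect_equal(self$best_reference, "CaGSTU1")
  # a moderately diverged descendant of the tau reference stays tau
  mut <- evolve_cds(sim$cds[[1]], omega = 0.4, expected_ds = 0.3, seed = 8)
  prot_mut <- gstfam:::.translate_cds(mut$seq)
  expect_equal(classify_member(prot_mut, refs, classes)$class_label, "tau")
  # exact tie between two classes warns and breaks lexicographically
  refs_tie <- seq_collection(c(b_ref = "MKVLA", a_ref = "MKVLA"), "protein")
  expect_warning(res <- classify_member("MKVLA", refs_tie, c("phi", "tau")),
                 "tie")
  expect_equal(res$best_reference, "a_ref")
  expect_error(classify_member("MKVLA", seq_collection(character(),
                                                       "protein")),
               "no references")
})

test_that("summarize_family reproduces the published tallies", {
  cat85 <- read_catalog_table(gst_table1_path())
  s <- summarize_family(cat85)
  expect_equal(as.integer(s$class_counts[c("tau", "phi", "theta", "zeta",
                                           "lambda", "EF1Bgamma", "DHAR",
                                           "TCHQD", "MGST", "GHR")]),
               c(59, 6, 4, 2, 4, 2, 2, 1, 2, 3))
  expect_equal(as.integer(s$chromosome_counts["9"]), 15)
  expect_equal(as.numeric(s$chromosome_pct["9"]), 17.6)
  st <- s$stats
  expect_equal(st$min[st$statistic == "gene_span_bp"], 306)
  expect_equal(st$max[st$statistic == "gene_span_bp"], 14430)
  expect_equal(st$min[st$statistic == "protein_aa"], 101)
  expect_equal(st$min[st$statistic == "mw_kda"], 11.62)
  expect_equal(st$max[st$statistic == "mw_kda"], 74.94)

  single <- cat85[1, ]
  class(single) <- class(cat85)
  s1 <- summarize_family(single)
  expect_true(all(s1$stats$min == s1$stats$max))
})

test_that("structure comparison classifies intron gain/loss", {
  a <- list(exons = rbind(c(1, 100), c(200, 300)))
  expect_equal(compare_structures(a, a)$classification, "same_count")
  b <- list(exons = rbind(c(1, 50), c(80, 150), c(200, 300)))
  expect_equal(compare_structures(a, b)$classification, "intron_gain")
  expect_equal(compare_structures(b, a)$classification, "intron_loss")
  expect_equal(compare_structures(a, b)$exon_delta, 1)
  expect_error(compare_structures(list(exons = matrix(ncol = 2, nrow = 0)),
                                  a), "empty exon")
  # planted pair in the simulator: gene 2 gained an intron relative to 1
  sim <- get_sim()
  exons_of <- function(g) {
    fs <- sim$features
    list(exons = as.matrix(fs[fs$type == "exon" &
                                fs$parent == paste0(g, ".1"),
                              c("start", "end")]))
  }
  pair <- sim$truth$intron_gain_pair
  expect_equal(compare_structures(exons_of(pair[1]),
                                  exons_of(pair[2]))$classification,
               "intron_gain")
})
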