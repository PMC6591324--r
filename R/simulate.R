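# Two-species gene-family simulator with planted ground truth.
# Every pipeline stage (catalog, duplication, dN/dS, reconciliation,
# expression, promoter scanning) can be closed against a dataset emitted
# here, with no external downloads.

#' Simulate post-split birth-death evolution of a gene family
#'
#' Each of `ancestral_count` ancestral genes evolves independently in each
#' of the two lineages after the species split: a linear birth-death
#' process (per-copy gain rate, per-copy loss rate) runs for `split_age`
#' time units. Surviving copies become leaves of the emitted gene tree;
#' units extinct in one lineage appear as single-species clades, units
#' extinct in both are absent from the tree (recorded in the truth).
#'
#' @param ancestral_count number of ancestral genes A (>= 1).
#' @param gain_rate,loss_rate per-copy event rates (>= 0), per unit time;
#'   length 1 (both lineages) or 2 (one rate per species).
#' @param split_age elapsed time since the split (default 36, the
#'   approximate pepper-tomato divergence in My).
#' @param seed integer RNG seed.
#' @param species character(2) species tags (default P = pepper-like,
#'   T = tomato-like).
#' @param cap maximum tolerated expected family size per lineage.
#' @return list `tree` (ape phylo, NULL if < 2 surviving leaves),
#'   `truth`: list with per-unit copy numbers and per-species
#'   extant/gains/losses tallies at tree level (visible units) and in
#'   total (including doubly-extinct units).
#' @export
simulate_family <- function(ancestral_count, gain_rate = 0.02,
                            loss_rate = 0.02, split_age = 36,
                            seed = 1, species = c("P", "T"),
                            cap = 5000) {
  gain_rate <- rep(gain_rate, length.out = 2)
  loss_rate <- rep(loss_rate, length.out = 2)
  stopifnot(ancestral_count >= 1, all(gain_rate >= 0), all(loss_rate >= 0),
            split_age >= 0, length(species) == 2)
  expected <- ancestral_count * exp((max(gain_rate) - min(loss_rate)) *
                                      split_age)
  if (expected > cap)
    stop("expected family size ", round(expected),
         " exceeds cap ", cap, "; lower the rates")
  set.seed(as.integer(seed))
  bd_copies <- function(g, l) {
    n <- 1L; t <- 0
    repeat {
      if (n == 0L) return(0L)
      rate <- n * (g + l)
      if (rate == 0) return(n)
      t <- t + stats::rexp(1, rate)
      if (t > split_age) return(n)
      if (stats::runif(1) < g / (g + l)) n <- n + 1L else n <- n - 1L
      if (n > cap) stop("family size cap exceeded during simulation")
    }
  }
  units <- data.frame(unit = seq_len(ancestral_count),
                      n_a = NA_integer_, n_b = NA_integer_)
  for (u in seq_len(ancestral_count)) {
    units$n_a[u] <- bd_copies(gain_rate[1], loss_rate[1])
    units$n_b[u] <- bd_copies(gain_rate[2], loss_rate[2])
  }
  # caterpillar clade of k leaves for species s in unit u
  clade <- function(s, u, k) {
    leaves <- sprintf("%s|u%02dg%d", s, u, seq_len(k))
    Reduce(function(a, b) paste0("(", a, ",", b, ")"), leaves)
  }
  both_nwk <- character(0); a_nwk <- character(0); b_nwk <- character(0)
  for (u in seq_len(ancestral_count)) {
    na <- units$n_a[u]; nb <- units$n_b[u]
    if (na == 0 && nb == 0) next
    if (na > 0 && nb > 0) {
      both_nwk <- c(both_nwk,
                    paste0("(", clade(species[1], u, na), ",",
                           clade(species[2], u, nb), ")"))
    } else if (na > 0) a_nwk <- c(a_nwk, clade(species[1], u, na))
    else b_nwk <- c(b_nwk, clade(species[2], u, nb))
  }
  # join order matters for species-overlap decomposition: anchoring the
  # chain on a two-species unit (and interleaving single-species units)
  # keeps every join node two-species, so units are exactly recoverable;
  # adjacent same-species-only units would merge into one apparent unit.
  interleave <- function(x, y) {
    out <- character(0)
    while (length(x) || length(y)) {
      if (length(x)) { out <- c(out, x[1]); x <- x[-1] }
      if (length(y)) { out <- c(out, y[1]); y <- y[-1] }
    }
    out
  }
  unit_nwk <- if (length(both_nwk))
    c(both_nwk[1], interleave(a_nwk, b_nwk), both_nwk[-1])
  else interleave(a_nwk, b_nwk)
  tree <- NULL
  n_leaves <- sum(units$n_a) + sum(units$n_b)
  if (n_leaves >= 2) {
    nwk <- Reduce(function(a, b) paste0("(", a, ",", b, ")"), unit_nwk)
    tree <- ape::read.tree(text = paste0(nwk, ";"))
  }
  vis <- units$n_a > 0 | units$n_b > 0
  tally <- function(n_self, n_other) {
    with_self <- sum(vis & n_self > 0)
    list(extant = sum(n_self),
         gains = sum(n_self) - with_self,
         losses_tree = sum(vis) - with_self,
         losses_total = ancestral_count - with_self)
  }
  truth <- list(
    ancestral_count = ancestral_count,
    units_in_tree = sum(vis),
    # species-overlap decomposition is only well-posed when some unit
    # survived in both species; otherwise single-species units of
    # opposite species merge into apparent speciation units
    identifiable = length(both_nwk) > 0,
    per_unit = units,
    species = stats::setNames(list(tally(units$n_a, units$n_b),
                                   tally(units$n_b, units$n_a)), species),
    gain_rate = gain_rate, loss_rate = loss_rate,
    split_age = split_age, rng_seed = as.integer(seed))
  list(tree = tree, truth = truth)
}

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Random in-frame CDS
#'
#' ATG start, random non-stop, non-ATG-free body; no terminal stop (the
#' simulator works with stop-free coding sequence).
#'
#' @param n_codons total codon count (>= 2).
#' @return CDS string.
#' @export
random_cds <- function(n_codons = 300) {
  stopifnot(n_codons >= 2)
  body <- sample(.sense_codons(), n_codons - 1, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""))
}

# Per-codon lookup of the non-stop single-nucleotide changes, split into
# synonymous and nonsynonymous, built once per session.
.codon_change_env <- new.env(parent = emptyenv())

.codon_change_table <- function() {
  if (!is.null(.codon_change_env$tab)) return(.codon_change_env$tab)
  tab <- list()
  for (cod in names(Biostrings::GENETIC_CODE)) {
    aa <- .translate_codon(cod)
    if (aa == "*") next
    chars <- strsplit(cod, "")[[1]]
    syn_p <- integer(0); syn_a <- character(0)
    non_p <- integer(0); non_a <- character(0)
    for (p in 1:3) {
      for (alt in setdiff(.nt, chars[p])) {
        mut <- chars; mut[p] <- alt
        maa <- .translate_codon(paste(mut, collapse = ""))
        if (maa == "*") next
        if (maa == aa) { syn_p <- c(syn_p, p); syn_a <- c(syn_a, alt) }
        else { non_p <- c(non_p, p); non_a <- c(non_a, alt) }
      }
    }
    tab[[cod]] <- list(syn = list(pos = syn_p, alt = syn_a),
                       non = list(pos = non_p, alt = non_a))
  }
  .codon_change_env$tab <- tab
  tab
}

# enumerate single-nucleotide changes of `type` ("syn"/"non") available in
# a codon vector; returns list(pos = CDS positions, alt = replacement base)
.candidate_changes <- function(codons, type) {
  tab <- .codon_change_table()
  pos <- vector("list", length(codons)); alt <- pos
  for (ci in seq_along(codons)) {
    e <- tab[[codons[ci]]][[type]]
    if (length(e$pos)) {
      pos[[ci]] <- (ci - 1L) * 3L + e$pos
      alt[[ci]] <- e$alt
    }
  }
  list(pos = unlist(pos), alt = unlist(alt))
}

#' Evolve a coding sequence at a controlled omega and dS
#'
#' Substitution counts are drawn as Poisson(expected_ds * S) synonymous
#' and Poisson(omega * expected_ds * N) nonsynonymous events (S, N the
#' Nei-Gojobori site counts of the ancestor); events are applied in random
#' interleaved order, each picking uniformly among the currently available
#' single-nucleotide changes of its type (stop codons never created).
#'
#' @param ancestor in-frame CDS (no internal stops).
#' @param omega target dN/dS (>= 0).
#' @param expected_ds target synonymous substitutions per site (>= 0).
#' @param seed optional integer seed (NULL = use current RNG state).
#' @return list `seq` (descendant CDS), `n_syn`, `n_non` (realized event
#'   counts), `S`, `N` (ancestor site counts).
#' @export
evolve_cds <- function(ancestor, omega, expected_ds, seed = NULL) {
  stopifnot(omega >= 0, expected_ds >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sites <- count_sites(ancestor)
  n_syn <- stats::rpois(1, expected_ds * sites["S"])
  n_non <- stats::rpois(1, omega * expected_ds * sites["N"])
  events <- sample(c(rep("syn", n_syn), rep("non", n_non)))
  codons <- .split_codons(ancestor)
  for (ev in events) {
    cand <- .candidate_changes(codons, ev)
    if (length(cand$pos) == 0) next
    k <- sample.int(length(cand$pos), 1)
    ci <- (cand$pos[k] - 1L) %/% 3L + 1L
    p <- (cand$pos[k] - 1L) %% 3L + 1L
    substr(codons[ci], p, p) <- cand$alt[k]
  }
  seq <- paste(codons, collapse = "")
  list(seq = seq, n_syn = as.integer(n_syn), n_non = as.integer(n_non),
       S = as.numeric(sites["S"]), N = as.numeric(sites["N"]))
}

.random_dna <- function(n) paste(sample(.nt, n, replace = TRUE), collapse = "")

# Remove every catalog-element match from a DNA string by mutating one
# base inside each hit, iterating until the scan is clean.
.scrub_elements <- function(seq, elements, max_iter = 60) {
  for (it in seq_len(max_iter)) {
    hits <- scan_elements(seq, elements, both_strands = TRUE)
    if (nrow(hits) == 0) return(seq)
    for (h in seq_len(nrow(hits))) {
      el <- elements$consensus[elements$name == hits$element[h]]
      width <- nchar(el)
      pos <- hits$position[h] + (width %/% 2)
      cur <- substr(seq, pos, pos)
      substr(seq, pos, pos) <- setdiff(.nt, cur)[1 + (pos %% 3)]
    }
  }
  stop("could not scrub promoter background of spurious element matches")
}

#' Simulate a complete two-species dataset with planted truth
#'
#' Builds, under one seed: a family gene tree ([simulate_family()]); a
#' pepper-like genome with planted tandem pairs (20-kb gap, same
#' chromosome), segmental pairs (different chromosomes) and singleton
#' genes, each pair evolved from its founder CDS at a planted omega and
#' dS ([evolve_cds()]); an intron-gain structure pair; promoters scrubbed
#' of spurious matches and planted with known element counts; and tissue
#' and stress expression matrices with planted tiers and responders.
#'
#' @param seed integer seed; the entire dataset is a deterministic
#'   function of it.
#' @param ancestral_count,gain_rate,loss_rate,split_age family-tree
#'   parameters (see [simulate_family()]).
#' @param n_tandem,n_segmental,n_singleton planted gene-architecture
#'   counts.
#' @param n_codons founder CDS length in codons.
#' @param omega_pair,ds_pair planted selection regime for duplicate pairs
#'   (purifying omega, one dS per pair recycled as needed).
#' @return a `gst_sim` list: `genome`, `features`, `catalog`, `cds`,
#'   `proteins`, `promoters`, `expr_tissue`, `expr_stress`, `tree`,
#'   `truth`.
#' @export
simulate_dataset <- function(seed = 1,
                             ancestral_count = 10,
                             gain_rate = 0.02, loss_rate = 0.02,
                             split_age = 36,
                             n_tandem = 3, n_segmental = 3,
                             n_singleton = 4,
                             n_codons = 300,
                             omega_pair = 0.3,
                             ds_pair = c(0.08, 0.15, 0.25)) {
  fam <- simulate_family(ancestral_count, gain_rate, loss_rate, split_age,
                         seed = seed)
  set.seed(as.integer(seed) + 1L)
  elements <- default_cis_elements()

  n_pairs <- n_tandem + n_segmental
  n_genes <- 2 * n_pairs + n_singleton
  gene_names <- sprintf("CaGSTU%d", seq_len(n_genes))

  # founders and descendants
  cds <- character(n_genes)
  pair_rows <- list()
  ds_cycle <- rep(ds_pair, length.out = n_pairs)
  gi <- 1
  for (p in seq_len(n_pairs)) {
    founder <- random_cds(n_codons)
    ev <- evolve_cds(founder, omega = omega_pair, expected_ds = ds_cycle[p])
    cds[gi] <- founder
    cds[gi + 1] <- ev$seq
    pair_rows[[p]] <- data.frame(
      gene_a = gene_names[gi], gene_b = gene_names[gi + 1],
      mode = if (p <= n_tandem) "tandem" else "segmental",
      omega = omega_pair, expected_ds = ds_cycle[p],
      n_syn = ev$n_syn, n_non = ev$n_non, stringsAsFactors = FALSE)
    gi <- gi + 2
  }
  for (s in seq_len(n_singleton)) {
    cds[gi] <- random_cds(n_codons)
    gi <- gi + 1
  }
  proteins <- vapply(cds, .translate_cds, character(1), USE.NAMES = FALSE)
  pairs_truth <- do.call(rbind, pair_rows)

  # genomic placement: tandem partners 20 kb apart on one chromosome,
  # segmental partners on different chromosomes, everything else spaced
  # 150 kb so no unplanted cluster or tandem call can arise
  n_chrom <- 3L
  placement <- data.frame(gene = gene_names, chrom = NA_integer_,
                          stringsAsFactors = FALSE)
  slot <- stats::setNames(rep(1L, n_chrom), seq_len(n_chrom))
  cursor <- stats::setNames(rep(200000L, n_chrom), seq_len(n_chrom))
  step <- 150000L
  coords <- data.frame(gene = gene_names, chrom = NA_integer_,
                       start = NA_integer_, end = NA_integer_,
                       strand = NA_character_, stringsAsFactors = FALSE)
  cds_len <- nchar(cds)
  place <- function(g, chrom, start, strand = "+") {
    i <- match(g, coords$gene)
    coords$chrom[i] <<- chrom
    coords$start[i] <<- start
    coords$end[i] <<- start + cds_len[i] - 1L
    coords$strand[i] <<- strand
  }
  chrom_rr <- 0L
  gi <- 1
  for (p in seq_len(n_pairs)) {
    if (p <= n_tandem) {
      chrom <- (chrom_rr %% n_chrom) + 1L; chrom_rr <- chrom_rr + 1L
      place(gene_names[gi], chrom, cursor[chrom])
      gap_start <- cursor[chrom] + cds_len[gi] - 1L + 20000L
      place(gene_names[gi + 1], chrom, gap_start, strand = "-")
      cursor[chrom] <- gap_start + cds_len[gi + 1] + step
    } else {
      c1 <- (chrom_rr %% n_chrom) + 1L
      c2 <- (c1 %% n_chrom) + 1L
      chrom_rr <- chrom_rr + 1L
      place(gene_names[gi], c1, cursor[c1]); cursor[c1] <- cursor[c1] + cds_len[gi] + step
      place(gene_names[gi + 1], c2, cursor[c2]); cursor[c2] <- cursor[c2] + cds_len[gi + 1] + step
    }
    gi <- gi + 2
  }
  while (gi <= n_genes) {
    chrom <- (chrom_rr %% n_chrom) + 1L; chrom_rr <- chrom_rr + 1L
    place(gene_names[gi], chrom, cursor[chrom])
    cursor[chrom] <- cursor[chrom] + cds_len[gi] + step
    gi <- gi + 1
  }

  # chromosomes: random background, genes and scrubbed+planted promoters
  # overwritten in place
  chrom_len <- vapply(seq_len(n_chrom), function(ch) {
    ends <- coords$end[coords$chrom == ch]
    max(c(ends, 250000L)) + 5000L
  }, integer(1))
  genome_seqs <- vapply(chrom_len, .random_dna, character(1))
  names(genome_seqs) <- sprintf("chr%d", seq_len(n_chrom))
  for (i in seq_len(n_genes)) {
    ch <- coords$chrom[i]
    body <- if (coords$strand[i] == "+") cds[i] else revcomp(cds[i])
    substr(genome_seqs[ch], coords$start[i], coords$end[i]) <- body
  }

  # promoters: plant a known count of a few elements per gene
  plant_els <- c("MBS", "ABRE", "HSE", "TGACG-motif", "LTR")
  upstream_len <- 1000L
  promoters <- character(n_genes); names(promoters) <- gene_names
  planted_counts <- matrix(0L, n_genes, length(plant_els),
                           dimnames = list(gene_names, plant_els))
  for (i in seq_len(n_genes)) {
    counts <- stats::setNames(sample(0:2, length(plant_els), replace = TRUE),
                              plant_els)
    for (try in 1:25) {
      prom <- .scrub_elements(.random_dna(upstream_len), elements)
      offs <- seq(20, by = 45, length.out = sum(counts))
      k <- 0
      for (el in plant_els) {
        cons <- elements$consensus[elements$name == el]
        for (r in seq_len(counts[el])) {
          k <- k + 1
          substr(prom, offs[k], offs[k] + nchar(cons) - 1) <- cons
        }
      }
      got <- element_count_matrix(stats::setNames(list(prom), "x"),
                                  elements)$counts
      if (all(got[1, plant_els] == counts) &&
          sum(got[1, ]) == sum(counts)) break
      if (try == 25) stop("could not plant promoter elements cleanly")
    }
    promoters[i] <- prom
    planted_counts[i, ] <- counts
    # write the promoter into the genome upstream of the gene
    ch <- coords$chrom[i]
    if (coords$strand[i] == "+") {
      substr(genome_seqs[ch], coords$start[i] - upstream_len,
             coords$start[i] - 1L) <- prom
    } else {
      substr(genome_seqs[ch], coords$end[i] + 1L,
             coords$end[i] + upstream_len) <- revcomp(prom)
    }
  }

  # gene models; one planted intron-gain pair: the second tandem copy of
  # pair 1 is annotated with 2 exons (its partner has 1)
  feat <- list()
  for (i in seq_len(n_genes)) {
    g <- gene_names[i]; ch <- sprintf("chr%d", coords$chrom[i])
    mid <- coords$start[i] + floor(cds_len[i] / 2)
    two_exon <- (i == 2L)
    feat[[length(feat) + 1]] <- data.frame(
      seqid = ch, source = "gstfam-sim", type = "gene",
      start = coords$start[i], end = coords$end[i],
      strand = coords$strand[i], phase = NA_integer_,
      id = g, parent = NA_character_, stringsAsFactors = FALSE)
    feat[[length(feat) + 1]] <- data.frame(
      seqid = ch, source = "gstfam-sim", type = "mRNA",
      start = coords$start[i], end = coords$end[i],
      strand = coords$strand[i], phase = NA_integer_,
      id = paste0(g, ".1"), parent = g, stringsAsFactors = FALSE)
    spans <- if (two_exon)
      rbind(c(coords$start[i], mid), c(mid + 1L, coords$end[i]))
    else rbind(c(coords$start[i], coords$end[i]))
    for (e in seq_len(nrow(spans))) {
      for (ty in c("exon", "CDS")) {
        feat[[length(feat) + 1]] <- data.frame(
          seqid = ch, source = "gstfam-sim", type = ty,
          start = spans[e, 1], end = spans[e, 2],
          strand = coords$strand[i],
          phase = if (ty == "CDS") 0L else NA_integer_,
          id = paste0(g, ".1.", ty, e), parent = paste0(g, ".1"),
          stringsAsFactors = FALSE)
      }
    }
  }
  features <- validate_features(do.call(rbind, feat))

  # catalog in the fixture schema
  catalog <- data.frame(
    gene_name = gene_names,
    locus_id = sprintf("Capana%02dg%06d", coords$chrom, seq_len(n_genes)),
    cds_start = coords$start, cds_end = coords$end,
    strand = coords$strand,
    gene_bp = cds_len,
    protein_aa = nchar(proteins),
    mw_kda = round(vapply(proteins, molecular_weight, numeric(1),
                          USE.NAMES = FALSE), 2),
    pi = round(vapply(proteins, isoelectric_point, numeric(1),
                      USE.NAMES = FALSE), 2),
    stringsAsFactors = FALSE)
  catalog$class_label <- class_from_name(catalog$gene_name)
  catalog$chromosome <- coords$chrom
  class(catalog) <- c("gst_catalog", "data.frame")

  # expression: planted tiers (10x separation) and stress responders
  # planted tier group sizes match the tertile rule of assign_tier so
  # recovery can be exact at the planted 10x+ separation
  n_low <- floor(n_genes / 3)
  n_med <- floor(2 * n_genes / 3) - n_low
  tiers <- stats::setNames(
    sample(c(rep("low", n_low), rep("medium", n_med),
             rep("high", n_genes - n_low - n_med))),
    gene_names)
  tier_mean <- c(low = 2, medium = 40, high = 800)
  tissues <- c("seedling", "flower", "ovary", "fruit", "seed", "root")
  expr_tissue <- t(vapply(gene_names, function(g) {
    base <- tier_mean[[as.character(tiers[g])]]
    round(base * exp(stats::runif(length(tissues), -0.25, 0.25)), 3)
  }, numeric(length(tissues))))
  colnames(expr_tissue) <- tissues

  timepoints <- c("0h", "1h", "1.5h", "3h", "6h", "12h", "24h")
  responders <- gene_names[seq_len(n_genes) %% 3 == 1]
  ramp <- c(1, 1.5, 2, 3, 4, 6, 8)
  expr_stress <- t(vapply(gene_names, function(g) {
    base <- tier_mean[[as.character(tiers[g])]]
    fc <- if (g %in% responders) ramp else rep(1, length(timepoints))
    round(base * fc * exp(stats::runif(length(timepoints), -0.05, 0.05)), 3)
  }, numeric(length(timepoints))))
  colnames(expr_stress) <- timepoints
  # exact control column so fold_change(control = "0h") is clean
  expr_stress[, "0h"] <- tier_mean[as.character(tiers[gene_names])]

  truth <- list(
    rng_seed = as.integer(seed),
    family = fam$truth,
    pairs = pairs_truth,
    intron_gain_pair = c(gene_names[1], gene_names[2]),
    planted_elements = planted_counts,
    tiers = as.character(tiers),
    tier_genes = gene_names,
    responders = responders,
    upstream_len = upstream_len)

  structure(list(genome = seq_collection(genome_seqs, "dna"),
                 features = features, catalog = catalog,
                 cds = seq_collection(stats::setNames(cds, gene_names), "dna"),
                 proteins = seq_collection(stats::setNames(proteins, gene_names),
                                           "protein"),
                 promoters = promoters,
                 expr_tissue = expr_tissue, expr_stress = expr_stress,
                 tree = fam$tree, truth = truth),
            class = "gst_sim")
}

#' Write a simulated dataset to disk
#'
#' Emits genome FASTA, GFF3, CDS and protein FASTA, promoter FASTA,
#' catalog TSV, tissue/stress expression TSVs, the family gene tree
#' (Newick) and the truth as JSON. Deterministic: the same `gst_sim`
#' object always produces byte-identical files.
#'
#' @param sim a `gst_sim` from [simulate_dataset()].
#' @param out_dir output directory.
#' @param force overwrite a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
emit_dataset <- function(sim, out_dir, force = FALSE) {
  stopifnot(inherits(sim, "gst_sim"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_fasta(sim$genome, p("genome.fna"))
  write_fasta(sim$cds, p("cds.fna"))
  write_fasta(sim$proteins, p("proteins.faa"))
  write_fasta(seq_collection(sim$promoters, "dna"), p("promoters.fna"))
  write_gff3(sim$features, p("genes.gff3"))
  utils::write.table(sim$catalog[, c("gene_name", "locus_id", "cds_start",
                                     "cds_end", "strand", "gene_bp",
                                     "protein_aa", "mw_kda", "pi")],
                     p("catalog.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  wr_expr <- function(m, f) {
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr_expr(sim$expr_tissue, "expression_tissue.tsv")
  wr_expr(sim$expr_stress, "expression_stress.tsv")
  if (!is.null(sim$tree)) write_newick(sim$tree, p("family.nwk"))
  truth <- sim$truth
  truth$planted_elements <- as.data.frame(truth$planted_elements)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(out_dir)
}
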