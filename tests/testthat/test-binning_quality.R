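mk_hits <- function(categories, clades = NA) {
  n <- length(categories)
  data.frame(query = sprintf("c1.p%d", seq_len(n)),
             subject_category = as.character(categories),
             subject_clade = as.character(rep_len(clades, n)),
             pident = rep(60, n), bitscore = rep(100, n),
             evalue = rep(1e-20, n), stringsAsFactors = FALSE)
}

test_that("contig category assignment follows the 25% dominance rule", {
  # 3/12 = 25% meets "at least 25%" and strictly dominates 1/12
  h <- mk_hits(c(rep("Mirusviricota", 3), "Bacteria"))
  expect_equal(assign_contig_category(h, 12), "Mirusviricota")
  # ties fail strict dominance
  h2 <- mk_hits(c(rep("Mirusviricota", 3), rep("Bacteria", 3)))
  expect_equal(assign_contig_category(h2, 10), "UNASSIGNED")
  # no hits
  expect_equal(assign_contig_category(mk_hits(character(0)), 10),
               "UNASSIGNED")
  # just under the threshold
  h3 <- mk_hits(rep("Mirusviricota", 2))
  expect_equal(assign_contig_category(h3, 9), "UNASSIGNED")
  expect_error(assign_contig_category(h, 0), "n_proteins")
})

test_that("category assignment is invariant to protein order", {
  set.seed(5)
  h <- mk_hits(sample(c(rep("Mirusviricota", 4), rep("Bacteria", 2),
                        "Archaea")))
  base <- assign_contig_category(h, 10)
  for (i in 1:10) {
    perm <- h[sample(nrow(h)), ]
    expect_equal(assign_contig_category(perm, 10), base)
  }
})

test_that("clade assignment needs half the proteins on one clade", {
  h <- mk_hits(rep("Mirusviricota", 4), clades = "C1")
  expect_equal(assign_contig_clade(h, 8), "C1")
  h2 <- mk_hits(rep("Mirusviricota", 6), clades = c("C1", "C2"))
  expect_true(is.na(assign_contig_clade(h2, 8)))
  expect_true(is.na(assign_contig_clade(mk_hits(character(0)), 8)))
})

test_that("MAGs group by bin and clade with length bounds", {
  bins <- data.frame(bin_id = "b1", contig_id = c("c1", "c2", "c3"))
  asn <- data.frame(contig_id = c("c1", "c2", "c3"), n_proteins = 10,
                    category = "Mirusviricota",
                    clade = c("C1", "C2", "C1"),
                    stringsAsFactors = FALSE)
  lens <- c(c1 = 60e3, c2 = 55e3, c3 = 10e3)
  res <- build_mags(bins, asn, lens)
  expect_equal(nrow(res$mags), 2)
  expect_setequal(res$mags$clade, c("C1", "C2"))
  expect_equal(res$mags$total_length[res$mags$clade == "C1"], 70e3)
  # 45 kb rejected below the lower bound; 700 kb above the upper
  asn2 <- data.frame(contig_id = c("c1", "c2"), n_proteins = 5,
                     category = "Mirusviricota", clade = "C1")
  small <- build_mags(data.frame(bin_id = "b", contig_id = "c1"),
                      asn2[1, ], c(c1 = 45e3))
  expect_equal(nrow(small$mags), 0)
  expect_equal(small$rejected$reason, "below_min_len")
  big <- build_mags(data.frame(bin_id = "b", contig_id = "c1"),
                    asn2[1, ], c(c1 = 700e3))
  expect_equal(big$rejected$reason, "above_max_len")
  # boundary: exactly 50 kb and 650 kb are kept
  at50 <- build_mags(data.frame(bin_id = "b", contig_id = "c1"),
                     asn2[1, ], c(c1 = 50e3))
  expect_equal(nrow(at50$mags), 1)
  # sub-2.5 kb contigs are dropped upstream
  tinyc <- build_mags(bins, asn, c(c1 = 60e3, c2 = 55e3, c3 = 2000))
  expect_false("c3" %in% tinyc$members$contig_id)
  # a contig in two bins is an input error
  expect_error(build_mags(
    data.frame(bin_id = c("b1", "b2"), contig_id = c("c1", "c1")),
    asn, lens), "more than one bin")
})

test_that("distant-genome rescue applies the full filter cascade", {
  mk <- function(bin_len_kb, hit_frac, contig_kb = 60, cell_frac = 0.05) {
    n_other <- max(0, round(bin_len_kb - contig_kb))
    contigs <- data.frame(
      contig_id = c("mcp", "big"),
      length = c(5e3, contig_kb * 1e3), has_mcp = c(TRUE, FALSE))
    if (n_other > 0) {
      contigs <- rbind(contigs, data.frame(
        contig_id = paste0("f", seq_len(n_other)), length = 1e3,
        has_mcp = FALSE))
    }
    bins <- data.frame(bin_id = "b1", contig_id = contigs$contig_id)
    np <- 20
    proteins <- data.frame(
      protein_id = paste0("big.p", seq_len(np)), contig_id = "big")
    n_hit <- round(hit_frac * np)
    n_cell <- round(cell_frac * np)
    hits <- data.frame(
      query_contig_id = rep("big", n_hit),
      subject_category = c(rep("Bacteria", n_cell),
                           rep("Mirusviricota", n_hit - n_cell)))
    list(bins = bins, contigs = contigs, hits = hits, proteins = proteins)
  }
  # 800 kb bin, 10% hits, one 60 kb contig with 5% cellular best hits
  ok <- mk(800, 0.10)
  res <- rescue_distant_mags(ok$bins, ok$contigs, ok$hits, ok$proteins)
  expect_equal(nrow(res$mags), 1)
  expect_equal(res$mags$total_length, 60e3)
  expect_true(res$mags$putative)
  # bins over 1 Mb are excluded
  big <- mk(1200, 0.10)
  expect_equal(nrow(rescue_distant_mags(big$bins, big$contigs, big$hits,
                                        big$proteins)$mags), 0)
  # bins with a good level of hits are excluded
  hot <- mk(800, 0.50)
  expect_equal(nrow(rescue_distant_mags(hot$bins, hot$contigs, hot$hits,
                                        hot$proteins)$mags), 0)
  # cellular contigs are excluded
  cell <- mk(800, 0.15, cell_frac = 0.15)
  expect_equal(nrow(rescue_distant_mags(cell$bins, cell$contigs, cell$hits,
                                        cell$proteins)$mags), 0)
  # surviving contigs below 50 kb cumulative give no output
  short <- mk(300, 0.10, contig_kb = 40)
  expect_equal(nrow(rescue_distant_mags(short$bins, short$contigs,
                                        short$hits, short$proteins)$mags), 0)
})

test_that("sccg derivation collapses same-contig copies and thresholds", {
  mem <- rbind(
    data.frame(genome_id = "g1", contig_id = "g1c1", gene_id = "a1",
               cluster_id = "k1"),
    data.frame(genome_id = "g2", contig_id = "g2c1", gene_id = "a2",
               cluster_id = "k1"),
    data.frame(genome_id = "g3", contig_id = c("g3c1", "g3c2"),
               gene_id = c("a3", "a4"), cluster_id = "k1"),
    # same-contig duplicate collapses to a single copy
    data.frame(genome_id = "g1", contig_id = "g1c1",
               gene_id = c("b1", "b2"), cluster_id = "k2"),
    data.frame(genome_id = "g2", contig_id = "g2c1", gene_id = "b3",
               cluster_id = "k3"))
  res <- derive_sccg(mem, paste0("g", 1:4), clade = "C",
                     min_clade_size = 4)
  # k1: single copy in g1, g2 (2/4 = 50%), two copies in g3, absent g4
  expect_true("k1" %in% res$clusters)
  # k2: collapsed single copy in g1 only (1/4) -> not sccg
  expect_false("k2" %in% res$clusters)
  expect_equal(unname(res$counts["g3", "k1"]), 2L)
  expect_equal(unname(res$counts["g1", "k2"]), 1L)
  expect_warning(derive_sccg(mem, paste0("g", 1:4), clade = "C",
                             min_clade_size = 10), "fewer than")
})

test_that("sccg model vetting enforces the mean range and single-hit rule", {
  counts <- cbind(
    good = rep(1L, 10),
    high_mean = c(rep(2L, 6), rep(1L, 4)),        # mean 1.6
    low_single = c(rep(1L, 6), rep(0L, 2), 2L, 2L))  # mean 1.0, 60% single
  rownames(counts) <- paste0("g", 1:10)
  kept <- filter_sccg_models(counts)
  expect_equal(kept, "good")
  # boundary: mean 1.5 and 70% single-hit are retained
  counts2 <- cbind(edge = c(rep(2L, 5), rep(1L, 5)))  # mean 1.5, 50% single
  expect_equal(length(filter_sccg_models(counts2)), 0)
  counts3 <- cbind(edge = c(rep(1L, 7), 2L, 2L, 0L))  # mean 1.1, 70% single
  expect_equal(filter_sccg_models(counts3), "edge")
})

test_that("genome scoring implements completion minus redundancy", {
  # 100 sccg: 88 single, 3 double, 9 absent -> (91, 3, 88)
  counts <- c(rep(1L, 88), rep(2L, 3), rep(0L, 9))
  expect_equal(unname(score_genome(counts)), c(91, 3, 88))
  expect_equal(unname(score_genome(rep(1L, 50))), c(100, 0, 100))
  expect_equal(unname(score_genome(rep(0L, 50))), c(0, 0, 0))
  expect_error(score_genome(integer(0)), "empty sccg")
})

test_that("final filters use strict bounds and keep unscored genomes", {
  scores <- data.frame(
    genome_id = c("a", "b", "c", "d"),
    quality = c(49, 50, 90, NA), redundancy = c(0, 25, 26, NA),
    scored = c(TRUE, TRUE, TRUE, FALSE))
  kept <- final_filters(scores)
  expect_setequal(kept$genome_id, c("b", "d"))
  expect_true(kept$unscored[kept$genome_id == "d"])
})

test_that("dereplication links pairs by ANI and picks representatives", {
  genomes <- data.frame(genome_id = c("g1", "g2", "g3", "g4"),
                        length = c(100e3, 200e3, 150e3, 120e3),
                        quality = c(90, 70, NA, NA))
  ani <- data.frame(genome_a = c("g1", "g3"), genome_b = c("g2", "g4"),
                    ani = c(99, 97.5), aligned_fraction = c(0.30, 0.60))
  reps <- dereplicate(genomes, ani)
  # g1/g2 linked: higher quality wins despite smaller size
  expect_true("g1" %in% reps$genome_id)
  expect_false("g2" %in% reps$genome_id)
  # 97.5 is below the identity gate: both kept
  expect_true(all(c("g3", "g4") %in% reps$genome_id))
  # below the alignment-fraction gate: both kept
  ani2 <- data.frame(genome_a = "g1", genome_b = "g2", ani = 99,
                     aligned_fraction = 0.20)
  expect_equal(nrow(dereplicate(genomes, ani2)), 4)
  # no quality anywhere: largest genome wins
  g2 <- genomes; g2$quality <- NA
  reps2 <- dereplicate(g2, ani)
  expect_true("g2" %in% reps2$genome_id)
  # invariance to input order
  perm <- dereplicate(genomes[c(3, 1, 4, 2), ], ani[2:1, ])
  expect_equal(perm, reps)
})

test_that("iterative binning recruits contigs via the grown reference", {
  # contig A matches the initial reference; contig B only matches
  # proteins of A's MAG (recruited at iteration 2); contig C matches
  # nothing
  proteins <- data.frame(
    protein_id = c(paste0("A.p", 1:4), paste0("B.p", 1:4),
                   paste0("C.p", 1:4)),
    contig_id = rep(c("A", "B", "C"), each = 4))
  contigs <- data.frame(contig_id = c("A", "B", "C"), length = 60e3,
                        has_mcp = FALSE)
  bins <- data.frame(bin_id = c("b1", "b2", "b3"),
                     contig_id = c("A", "B", "C"))
  ref0 <- data.frame(protein_id = paste0("ref", 1:5),
                     category = "Mirusviricota", clade = "C1")
  link <- c(A.p1 = "ref1", A.p2 = "ref2", A.p3 = "ref3",
            B.p1 = "A.p1", B.p2 = "A.p2", B.p3 = "A.p3")
  backend <- function(prot, db) {
    tgt <- link[prot$protein_id]
    ok <- !is.na(tgt) & tgt %in% db$protein_id
    if (!any(ok)) return(empty <- data.frame(
      query = character(), query_contig_id = character(),
      subject_category = character(), subject_clade = character(),
      pident = numeric(), bitscore = numeric(), evalue = numeric()))
    data.frame(query = prot$protein_id[ok],
               query_contig_id = prot$contig_id[ok],
               subject_category = "Mirusviricota", subject_clade = "C1",
               pident = 60, bitscore = 150, evalue = 1e-30,
               stringsAsFactors = FALSE)
  }
  res0 <- iterate_binning(bins, contigs, proteins, ref0, backend,
                          n_iterations = 0, rescue = FALSE)
  expect_setequal(res0$members$contig_id, "A")
  res2 <- iterate_binning(bins, contigs, proteins, ref0, backend,
                          n_iterations = 2, rescue = FALSE)
  expect_setequal(res2$members$contig_id, c("A", "B"))
  # deterministic: same inputs give identical MAG sets
  res2b <- iterate_binning(bins, contigs, proteins, ref0, backend,
                           n_iterations = 2, rescue = FALSE)
  expect_identical(res2$mags, res2b$mags)
})

test_that("annotation and singleton percentages follow the definitions", {
  genes <- data.frame(genome_id = "g1", gene_id = paste0("x", 1:10))
  ann <- data.frame(gene_id = paste0("x", 1:10),
                    annotated = c(rep(TRUE, 4), rep(FALSE, 6)))
  # clusters: A has 3 genes, B has 2; x6 sits in a size-1 cluster and the
  # rest are unclustered -> 5 singletons
  clusters <- data.frame(gene_id = paste0("x", 1:6),
                         cluster_id = c("A", "A", "A", "B", "B", "solo"))
  res <- summarize_annotation(genes, ann, clusters)
  expect_equal(res$pct_annotated, 40)
  expect_equal(res$pct_singletons, 50)
  expect_error(summarize_annotation(
    genes, ann, rbind(clusters,
                      data.frame(gene_id = "x1", cluster_id = "B"))),
    "more than one cluster")
  expect_error(summarize_annotation(
    data.frame(genome_id = "g2", gene_id = character(0)), ann, clusters))
})
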