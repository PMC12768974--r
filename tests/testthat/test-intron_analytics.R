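test_that("intron density is introns per kb of gene footprint", {
  models <- data.frame(gene_id = c("g1", "g2"), contig_id = "c",
                       strand = "+", start = c(0, 3000),
                       end = c(2000, 6000), source = "x")
  introns <- data.frame(gene_id = rep(c("g1", "g2"), c(6, 4)))
  expect_equal(intron_density(models, introns), 2.0)
  expect_equal(intron_density(models, introns[0, , drop = FALSE]), 0)
  expect_error(intron_density(models, introns, scope = "absent"),
               "zero total")
})

test_that("enrichment ratios compare in- and out-of-class densities", {
  models <- data.frame(gene_id = c("m", "o"), contig_id = "c",
                       strand = "+", start = c(0, 2000),
                       end = c(1000, 3000), source = "x")
  introns <- data.frame(gene_id = c(rep("m", 4), rep("o", 2)))
  res <- enrichment_ratio(models, introns, "m")
  expect_equal(res$ratio, 2.0)
  expect_equal(res$intron_share_pct, 100 * 4 / 6)
  # equal densities give ratio 1
  introns2 <- data.frame(gene_id = c("m", "m", "o", "o"))
  expect_equal(enrichment_ratio(models, introns2, "m")$ratio, 1.0)
  # no introns outside the class: flagged infinite
  introns3 <- data.frame(gene_id = rep("m", 3))
  res3 <- enrichment_ratio(models, introns3, "m")
  expect_true(res3$infinite)
  expect_equal(res3$ratio, Inf)
  expect_error(enrichment_ratio(models, introns, c("m", "o")),
               "non-empty")
})

test_that("planted density enrichment is recovered from the community", {
  cfg <- community_config(
    seed = 17,
    clades = data.frame(clade = "cladeA", n_genomes = 3L, len_min = 300e3,
                        len_max = 450e3, gc = 0.45),
    intron_rate = 0.25, morph_fraction = 0.08, morph_intron_factor = 10,
    introner_families = 0L, paralog_decoy_pairs = 0L,
    nested_orf_count = 0L, trans_split = FALSE, singleton_families = 0L)
  comm <- generate_community(cfg)
  models <- truth_models(comm)
  ii <- extract_introns(models, comm$sequences)
  expect_gte(nrow(ii), 200)
  morph <- unique(comm$truth$genes$gene_id[comm$truth$genes$is_morph])
  # per-exonic-kb densities recover the planted rate ratio
  res <- enrichment_ratio(models, ii, morph, footprint = FALSE)
  expect_lt(abs(res$ratio - 10) / 10, 0.15)
  # on the genomic footprint the morphogenesis class stays strongly
  # enriched (the footprint denominator absorbs the extra intron bases)
  res_fp <- enrichment_ratio(models, ii, morph)
  expect_gt(res_fp$ratio, 5)
})

test_that("IUPAC motifs are honoured inside the acceptor window only", {
  # motif planted fully inside [-40, -10] from the intron 3' end
  mk_intron <- function(insert, at) {
    len <- 120
    interior <- strrep("G", len - 4)
    substr(interior, at - 2, at - 3 + nchar(insert)) <- insert
    data.frame(intron_id = "i", seq = paste0("GT", interior, "AG"),
               length = len, stringsAsFactors = FALSE)
  }
  inwin <- mk_intron("ACTAAC", 120 - 30)
  expect_equal(motif_fraction(inwin, "WCTAAC")$fraction, 1.0)
  # same motif outside the window does not count
  outwin <- mk_intron("ACTAAC", 20)
  expect_equal(motif_fraction(outwin, "WCTAAC")$fraction, 0.0)
  # TCTAAC also matches the W position
  expect_equal(motif_fraction(mk_intron("TCTAAC", 120 - 30),
                              "WCTAAC")$fraction, 1.0)
  # introns shorter than the window are skipped with a flag
  short <- data.frame(intron_id = "s", seq = paste0("GT", strrep("G", 20),
                                                    "AG"), length = 24)
  res <- motif_fraction(short, "WCTAAC")
  expect_equal(res$flags, "skipped")
  expect_true(is.na(res$fraction))
})

test_that("branch-motif discovery ranks the planted k-mer first", {
  set.seed(41)
  n <- 120
  mk <- function(planted) {
    interior <- vapply(seq_len(n), function(i) rand_seq(100), character(1))
    if (planted) {
      pos <- sample(66:85, n, replace = TRUE)  # inside [-40,-10]
      plant <- runif(n) < 0.6
      for (i in which(plant))
        substr(interior[i], pos[i], pos[i] + 4) <- "CTGAC"
    }
    data.frame(intron_id = paste0("i", seq_len(n)),
               seq = paste0("GT", interior, "AG"), length = 104,
               stringsAsFactors = FALSE)
  }
  res <- discover_branch_motif(mk(TRUE), n_shuffles = 20)
  expect_equal(res$motif[1], "CTGAC")
  expect_gt(res$fraction[1], 0.4)
  # uniform random introns: nothing beats the background
  expect_equal(nrow(discover_branch_motif(mk(FALSE), n_shuffles = 20)), 0)
  expect_error(discover_branch_motif(mk(TRUE)[1:10, ]), "at least 50")
})

test_that("the dinucleotide shuffle preserves dinucleotide counts", {
  set.seed(2)
  for (i in 1:10) {
    s <- rand_seq(60)
    sh <- mirusmine:::dinuc_shuffle(s)
    count_dinucs <- function(x) {
      ch <- strsplit(x, "")[[1]]
      sort(table(paste0(ch[-length(ch)], ch[-1])))
    }
    expect_equal(count_dinucs(sh), count_dinucs(s))
  }
})

test_that("the local aligner matches an independent DP oracle", {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  set.seed(13)
  for (i in 1:60) {
    a <- rand_seq(sample(8:40, 1))
    b <- rand_seq(sample(8:40, 1))
    mine <- align_local(a, b)$score
    oracle <- max(0, Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat, gapOpening = 5,
      gapExtension = 2, scoreOnly = TRUE))
    expect_equal(mine, oracle)
  }
  # related pairs (shared core) as well as random ones
  for (i in 1:20) {
    core <- rand_seq(20)
    a <- paste0(rand_seq(8), core, rand_seq(8))
    b <- paste0(rand_seq(5), core, rand_seq(10))
    mine <- align_local(a, b)$score
    oracle <- max(0, Biostrings::pairwiseAlignment(
      a, b, type = "local", substitutionMatrix = mat, gapOpening = 5,
      gapExtension = 2, scoreOnly = TRUE))
    expect_equal(mine, oracle)
  }
})

test_that("introner detection groups identical same-genome introns", {
  tmpl <- paste0("GT", rand_seq(81), "AG")
  mk <- function(id, genome, seq, up = rand_seq(10), dn = rand_seq(10)) {
    data.frame(intron_id = id, genome_id = genome, seq = seq,
               length = nchar(seq), upstream_flank = up,
               downstream_flank = dn, stringsAsFactors = FALSE)
  }
  # two identical introns, distinct genes, one genome -> one group of two
  introns <- rbind(mk("i1", "g1", tmpl), mk("i2", "g1", tmpl))
  grp <- detect_introners(introns)
  expect_equal(nrow(grp), 2)
  expect_equal(length(unique(grp$group)), 1)
  # identical introns in different genomes -> no group
  cross <- rbind(mk("i1", "g1", tmpl), mk("i2", "g2", tmpl))
  expect_equal(nrow(detect_introners(cross)), 0)
  # paralogous copies (identical flanks as well) -> excluded
  fl_u <- rand_seq(10); fl_d <- rand_seq(10)
  para <- rbind(mk("i1", "g1", tmpl, fl_u, fl_d),
                mk("i2", "g1", tmpl, fl_u, fl_d))
  expect_equal(nrow(detect_introners(para)), 0)
  # unrelated introns -> no group
  rand2 <- rbind(mk("i1", "g1", paste0("GT", rand_seq(81), "AG")),
                 mk("i2", "g1", paste0("GT", rand_seq(81), "AG")))
  expect_equal(nrow(detect_introners(rand2)), 0)
  expect_error(detect_introners(transform(introns, upstream_flank = "")),
               "flank")
})

test_that("introner detection on the community: planted families only", {
  comm <- tiny_community()
  ii <- truth_introns_extracted(comm)
  grp <- detect_introners(ii)
  planted <- ii$intron_id[ii$kind == "introner"]
  decoys <- ii$intron_id[ii$kind == "decoy"]
  expect_gte(mean(planted %in% grp$intron_id), 0.95)
  expect_true(all(grp$intron_id %in% planted))
  expect_false(any(decoys %in% grp$intron_id))
  expect_equal(length(unique(grp$group)),
               comm$config$introner_families)
  # invariant to intron input order
  grp2 <- detect_introners(ii[rev(seq_len(nrow(ii))), ])
  expect_identical(grp, grp2)
})

test_that("nested-ORF scanning obeys the length gates", {
  set.seed(3)
  # a 1200 bp intron with a planted 150-aa ORF
  orf <- paste0("ATG", mirusmine:::random_codons(150), "TAA")
  lead <- rand_seq(300)
  intron <- paste0("GT", lead, orf, rand_seq(1200 - 4 - 300 -
                                               nchar(orf)), "AG")
  introns <- data.frame(intron_id = "big", seq = intron,
                        length = nchar(intron), stringsAsFactors = FALSE)
  res <- find_nested_orfs(introns)
  expect_true("big" %in% res$intron_id)
  hit <- res[res$intron_id == "big" & res$strand == "+", ]
  expect_true(any(hit$aa_length >= 150))
  # introns of 250 bp are never scanned
  small <- data.frame(intron_id = "small",
                      seq = paste0("GT", rand_seq(246), "AG"), length = 250)
  expect_equal(nrow(find_nested_orfs(small)), 0)
  # a 90-aa ORF in a long intron is below the reporting gate
  orf90 <- paste0("ATG", mirusmine:::random_codons(90), "TAA")
  in90 <- paste0("GT", strrep("TAA", 40), orf90, strrep("TAA", 40), "AG")
  i90 <- data.frame(intron_id = "i90", seq = in90, length = nchar(in90))
  res90 <- find_nested_orfs(i90)
  expect_false(any(res90$aa_length <= 100))
})

test_that("planted nested ORFs are all recovered from the community", {
  comm <- tiny_community()
  ii <- truth_introns_extracted(comm)
  found <- find_nested_orfs(ii)
  truth <- comm$truth$nested_orfs
  key <- paste(comm$truth$introns$contig_id, comm$truth$introns$start,
               comm$truth$introns$end)
  truth_ids <- ii$intron_id[match(
    key[match(truth$intron_id, comm$truth$introns$intron_id)],
    paste(ii$contig_id, ii$start, ii$end))]
  for (k in seq_along(truth_ids)) {
    hit <- found[found$intron_id == truth_ids[k] &
                   found$strand == truth$orf_strand[k], ]
    expect_gte(max(c(hit$aa_length, 0)), truth$aa_length[k])
  }
  # nothing at or below the 300 bp intron gate was scanned
  short_ids <- ii$intron_id[ii$length <= 300]
  expect_false(any(found$intron_id %in% short_ids))
})

test_that("the specificity test is the Pearson chi-squared", {
  res <- target_specificity_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  flat <- target_specificity_test(matrix(c(5, 5, 5, 5), 2))
  expect_equal(flat$chi2, 0)
  expect_equal(flat$p, 1)
  expect_error(target_specificity_test(matrix(1:2, 1)), "2 x 2")
  expect_error(target_specificity_test(matrix(c(1, 1, 0, 0), 2)),
               "degenerate")
  # closed form agreement on random 2x2 tables
  set.seed(19)
  for (i in 1:200) {
    m <- matrix(sample(1:40, 4, replace = TRUE), 2)
    expect_equal(target_specificity_test(m)$chi2,
                 chi2_2x2_closed_form(m))
  }
})

test_that("trans-splice detection needs two genes and canonical sites", {
  seq <- paste0(rand_seq(1000),                      # [0,1000)
                strrep("A", 500),                    # gene A [1000,1500)
                "GT", rand_seq(30000 - 4), "AG",     # spacer
                strrep("C", 400),                    # gene B [31500,31900)
                rand_seq(500))
  models <- data.frame(
    gene_id = c("gA", "gB"), contig_id = "c", strand = "+",
    start = c(1000, 31500), end = c(1500, 31900), source = "x")
  jn <- data.frame(contig_id = "c", donor_pos = 1500,
                   acceptor_pos = 31500, donor_strand = "+",
                   acceptor_strand = "+", read_count = 12)
  ev <- detect_trans_splice(jn, models, c(c = seq))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$fragment_a, "gA")
  expect_equal(ev$fragment_b, "gB")
  expect_equal(ev$separation, 30000)
  expect_true(ev$same_strand)
  # below the read threshold: no event
  jn9 <- transform(jn, read_count = 9)
  expect_equal(nrow(detect_trans_splice(jn9, models, c(c = seq))), 0)
  # junction within a single gene is a cis intron, not an event
  jn_cis <- data.frame(contig_id = "c", donor_pos = 1100,
                       acceptor_pos = 1400, donor_strand = "+",
                       acceptor_strand = "+", read_count = 30)
  expect_equal(nrow(detect_trans_splice(jn_cis, models, c(c = seq))), 0)
  # non-canonical genomic dinucleotides: no event
  seq_bad <- seq
  substr(seq_bad, 1501, 1502) <- "CC"
  expect_equal(nrow(detect_trans_splice(jn, models, c(c = seq_bad))), 0)
})

test_that("opposite-strand trans-splice junctions are detected", {
  # donor side on plus strand gene, acceptor side on minus strand gene;
  # acceptor dinucleotide is the reverse complement at the acceptor side
  seq <- paste0(strrep("A", 500),          # gene A [0,500)
                "GT", rand_seq(4996),
                strrep("C", 400),          # gene B [5498,5898) minus
                rand_seq(100))
  # plant revcomp(AG) = CT just after the acceptor position
  substr(seq, 5499, 5500) <- "CT"
  models <- data.frame(
    gene_id = c("gA", "gB"), contig_id = "c", strand = c("+", "-"),
    start = c(0, 5498), end = c(500, 5898), source = "x")
  jn <- data.frame(contig_id = "c", donor_pos = 500,
                   acceptor_pos = 5498, donor_strand = "+",
                   acceptor_strand = "-", read_count = 15)
  ev <- detect_trans_splice(jn, models, c(c = seq))
  expect_equal(nrow(ev), 1)
  expect_false(ev$same_strand)
})

test_that("the planted trans-split pair is recovered and decoys rejected", {
  comm <- tiny_community()
  set.seed(23)
  jn <- generate_junctions(comm, decoy_fraction = 0.5)
  models <- truth_models(comm)
  ev <- detect_trans_splice(jn, models, comm$sequences)
  tp <- comm$truth$trans_pairs
  expect_equal(nrow(ev), 1)
  expect_equal(ev$fragment_a, tp$fragment_a)
  expect_equal(ev$fragment_b, tp$fragment_b)
  expect_equal(ev$separation, tp$separation)
})
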