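test_that("the generator is deterministic: same seed, same bytes", {
  cfg <- community_config(
    seed = 123,
    clades = data.frame(clade = "cladeA", n_genomes = 2L, len_min = 50e3,
                        len_max = 60e3, gc = 0.45))
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1$sequences, c2$sequences)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$hits, c2$hits)
})

test_that("configuration invariants are enforced", {
  expect_error(community_config(contamination = 1.3), "rates")
  expect_error(community_config(
    clades = data.frame(clade = "a", n_genomes = 1L, len_min = 100,
                        len_max = 500, gc = 0.5)), "1 kb")
  expect_error(community_config(branch_motif = "WXZ"), "IUPAC")
})

test_that("planted intron counts follow the configured rate", {
  comm <- mid_community()
  tr <- comm$truth
  plain <- tr$introns[tr$introns$kind == "plain", ]
  exonic_kb <- sum(tr$genes$end - tr$genes$start) / 1000
  lambda <- comm$config$intron_rate * exonic_kb  # ignores morph enrichment
  # planted count within generous Poisson bounds around the expectation
  expect_gt(nrow(plain), 0.5 * lambda)
  expect_lt(nrow(plain), 2.5 * lambda)
})

test_that("every planted feature appears exactly once and validates", {
  comm <- tiny_community()
  cfg <- comm$config
  tr <- comm$truth
  expect_equal(nrow(tr$introners),
               cfg$introner_families * cfg$introner_copies)
  expect_equal(length(unique(tr$introners$family)), cfg$introner_families)
  expect_equal(nrow(tr$decoy_pairs), 2L * cfg$paralog_decoy_pairs)
  expect_equal(nrow(tr$nested_orfs), cfg$nested_orf_count)
  expect_equal(nrow(tr$trans_pairs), 1L)
  expect_false(anyDuplicated(tr$introns$intron_id) > 0)
  lens <- vapply(comm$sequences, nchar, integer(1))
  expect_silent(validate_intervals(tr$introns, lens))
  expect_silent(validate_intervals(tr$genes, lens))
  expect_silent(validate_models(
    tr$genes[, c("gene_id", "contig_id", "strand", "start", "end")]))
})

test_that("generated files parse with the package readers", {
  comm <- tiny_community()
  dir <- withr::local_tempdir()
  write_community(comm, dir)
  seqs <- read_fasta(file.path(dir, "contigs.fasta"))
  expect_equal(sort(names(seqs)), sort(names(comm$sequences)))
  feats <- read_gff3(file.path(dir, "genes_truth.gff3"))
  models <- features_to_models(feats)
  tm <- truth_models(comm)
  expect_equal(sort(paste(models$contig_id, models$start, models$end)),
               sort(paste(tm$contig_id, tm$start, tm$end)))
  expect_s3_class(read_tree(file.path(dir, "clade_tree.nwk")), "phylo")
  expect_gt(nrow(read_ani(file.path(dir, "ani.tsv"))), 0)
})

test_that("intron sequences honour splice classes, motifs and lengths", {
  comm <- mid_community()
  ii <- truth_introns_extracted(comm)
  expect_equal(nrow(ii), nrow(comm$truth$introns))
  # by construction: class from truth matches the extracted dinucleotides
  expect_true(all(ii$splice_class[ii$truth_class == "major"] == "major"))
  expect_true(all(ii$splice_class[ii$truth_class == "minor"] == "minor"))
  # planted branch motifs are found in the search window
  planted <- ii[ii$has_motif %in% TRUE, ]
  mf <- motif_fraction(planted, comm$config$branch_motif)
  expect_true(all(mf$flags[mf$flags != "skipped"] == "match"))
})

test_that("empirical intron length mode sits near the configured mode", {
  cfg <- community_config(
    seed = 31,
    clades = data.frame(clade = "cladeA", n_genomes = 2L, len_min = 500e3,
                        len_max = 650e3, gc = 0.45),
    intron_rate = 0.7, introner_families = 0L, paralog_decoy_pairs = 0L,
    nested_orf_count = 0L, trans_split = FALSE, singleton_families = 0L,
    redundant_pairs = 0L)
  comm <- generate_community(cfg)
  lens <- comm$truth$introns$length
  expect_gte(length(lens), 500)
  # mode of the fitted log-normal length model (the generator's model):
  # exp(meanlog - sdlog^2)
  l <- log(lens)
  mode_hat <- exp(mean(l) - stats::var(l))
  expect_lt(abs(mode_hat - cfg$intron_length_mode), 10)
  # and the bulk of the distribution sits around the mode
  expect_gt(mean(lens >= 50 & lens <= 130), 0.9)
})

test_that("zero error rates reproduce the truth exon chains exactly", {
  comm <- tiny_community()
  preds <- generate_predictions(comm, c(fusion = 0, spurious = 0))
  tm <- truth_models(comm)
  expect_equal(
    sort(paste(preds$intron_aware$contig_id, preds$intron_aware$strand,
               preds$intron_aware$start, preds$intron_aware$end)),
    sort(paste(tm$contig_id, tm$strand, tm$start, tm$end)))
  expect_equal(nrow(preds$corruptions), 0)
})

test_that("planted corruptions have the advertised structure", {
  comm <- mid_community()
  set.seed(2)
  preds <- generate_predictions(comm)
  led <- preds$corruptions
  expect_gt(sum(led$type == "fusion"), 0)
  expect_gt(sum(led$type == "spurious_exon"), 0)
  for (i in which(led$type == "fusion")) {
    ex <- preds$intron_aware[preds$intron_aware$gene_id ==
                               led$corrupted_id[i], ]
    expect_equal(nrow(ex), 2)
    expect_true(all(ex$end - ex$start > 300))
    orig <- strsplit(led$original_ids[i], ",")[[1]]
    orf <- preds$orf[preds$orf$gene_id %in% paste0("orf_", orig), ]
    # each exon coincides with one original single-exon gene
    expect_setequal(paste(ex$start, ex$end), paste(orf$start, orf$end))
  }
  for (i in which(led$type == "spurious_exon")) {
    ex <- preds$intron_aware[preds$intron_aware$gene_id ==
                               led$corrupted_id[i], ]
    ex <- ex[order(ex$start), ]
    lens <- ex$end - ex$start
    expect_equal(nrow(ex), 2)
    expect_lt(min(lens), 0.05 * max(lens))
  }
})

test_that("junction tables reflect truth, coverage and decoys", {
  comm <- tiny_community()
  set.seed(3)
  jn <- generate_junctions(comm, coverage_mean = 30, decoy_fraction = 0.5)
  expect_true(all(jn$read_count[jn$truth == "decoy"] <= 9))
  # all decoys removed by the default evidence threshold
  kept <- filter_junctions(jn)
  expect_false(any(kept$truth == "decoy"))
  # exactly one junction joins the trans-spliced fragments, at the
  # planted separation
  trj <- jn[jn$truth == "trans", ]
  expect_equal(nrow(trj), 1)
  expect_equal(trj$acceptor_pos - trj$donor_pos,
               comm$truth$trans_pairs$separation)
  # zero coverage with decoys off gives an empty table
  empty <- generate_junctions(comm, coverage_mean = 0, decoy_fraction = 0)
  expect_equal(nrow(empty), 0)
})
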