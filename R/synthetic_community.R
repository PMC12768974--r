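#' Configuration of a synthetic mirusvirus community
#'
#' Builds the parameter set for [generate_community()]. Defaults emulate
#' protist-infecting virus genomes: 50-650 kb genomes in three clades,
#' genes carrying GT-AG spliceosomal introns with a length distribution
#' peaking near 80 bp, a small AT-AC minor-spliceosome class, a
#' branch-point motif planted upstream of acceptor sites, families of
#' near-identical introns (introners), open reading frames nested inside
#' long introns, one terminase gene split into two distant trans-spliced
#' fragments, and metagenomic bins contaminated with cellular contigs.
#'
#' @param seed integer seed; the same configuration and seed give
#'   byte-identical output.
#' @param clades data frame with columns `clade`, `n_genomes`, `len_min`,
#'   `len_max`, `gc`.
#' @param gene_density genes per kb of genome.
#' @param mean_gene_len mean exonic gene length (bp).
#' @param intron_rate introns per kb of exonic gene sequence.
#' @param morph_fraction fraction of genes labelled as virion morphogenesis
#'   genes.
#' @param morph_intron_factor fold enrichment of the intron rate in
#'   morphogenesis genes.
#' @param intron_length_mode,intron_length_sdlog mode (bp) and log-scale
#'   spread of the log-normal intron length model.
#' @param minor_splice_fraction fraction of AT-AC (minor spliceosome)
#'   introns.
#' @param branch_motif IUPAC branch-point motif planted upstream of
#'   acceptors.
#' @param branch_motif_fraction fraction of introns carrying the motif.
#' @param branch_window window, relative to the intron 3' end, in which the
#'   motif is planted (and searched by default).
#' @param introner_families,introner_copies,introner_length introner family
#'   count, identical copies per family, and template length (bp). All
#'   families are planted in one genome.
#' @param paralog_decoy_pairs pairs of introns with identical sequence
#'   *and* identical 10 bp exon flanks, emulating paralogous gene copies
#'   that must be rejected by the flank-extension rule.
#' @param nested_orf_count planted open reading frames (>100 aa) inside
#'   long (>300 bp) introns, distributed over the community.
#' @param nested_aa_range amino-acid length range of planted nested ORFs.
#' @param trans_split logical: plant one terminase split into two
#'   trans-spliced fragments.
#' @param trans_separation genomic separation of the two fragments (bp).
#' @param contamination fraction of cellular contigs per bin.
#' @param hit_fraction fraction of viral proteins receiving a reference
#'   best hit.
#' @param cellular_hit_fraction fraction of cellular-contig proteins with a
#'   cellular best hit.
#' @param prediction_error_rates named vector `c(fusion = , spurious = )`
#'   of planted gene-prediction error rates.
#' @param sccg_per_clade,sccg_missing_rate,sccg_dup_rate single-copy
#'   core-gene clusters per clade and their per-genome missing/duplication
#'   rates.
#' @param families_per_clade,singleton_families planted taxonomic families
#'   per clade and number of genomes placed on long branches as
#'   single-genome families.
#' @param redundant_pairs genome pairs planted as redundant (ANI >= 98,
#'   aligned fraction >= 0.25) in the ANI table.
#' @param annotation_rate fraction of genes with a functional annotation.
#' @param min_contig smallest contig size emitted (bp).
#' @return a `community_config` list.
#' @export
community_config <- function(
    seed = 1L,
    clades = data.frame(
      clade = c("Demutovirales", "Okeanovirales", "Styxvirales"),
      n_genomes = c(7L, 7L, 6L),
      len_min = 50e3, len_max = 650e3,
      gc = c(0.35, 0.45, 0.55)),
    gene_density = 0.7,
    mean_gene_len = 800,
    intron_rate = 0.2,
    morph_fraction = 0.05,
    morph_intron_factor = 10,
    intron_length_mode = 80,
    intron_length_sdlog = 0.25,
    minor_splice_fraction = 0.03,
    branch_motif = "WCTAAC",
    branch_motif_fraction = 0.35,
    branch_window = c(-40, -10),
    introner_families = 3L,
    introner_copies = 5L,
    introner_length = 85L,
    paralog_decoy_pairs = 2L,
    nested_orf_count = 8L,
    nested_aa_range = c(110L, 200L),
    trans_split = TRUE,
    trans_separation = 30000L,
    contamination = 0.30,
    hit_fraction = 0.8,
    cellular_hit_fraction = 0.7,
    prediction_error_rates = c(fusion = 0.1, spurious = 0.1),
    sccg_per_clade = 60L,
    sccg_missing_rate = 0.03,
    sccg_dup_rate = 0.02,
    families_per_clade = 3L,
    singleton_families = 2L,
    redundant_pairs = 1L,
    annotation_rate = 0.25,
    min_contig = 2500L) {
  cfg <- as.list(environment())
  check_columns(clades, c("clade", "n_genomes", "len_min", "len_max", "gc"),
                "clade table")
  rates <- c(cfg$morph_fraction, cfg$minor_splice_fraction,
             cfg$branch_motif_fraction, cfg$contamination, cfg$hit_fraction,
             cfg$cellular_hit_fraction, cfg$prediction_error_rates,
             cfg$sccg_missing_rate, cfg$sccg_dup_rate, cfg$annotation_rate)
  if (any(rates < 0 | rates > 1))
    stop("all rates must lie in [0, 1]")
  if (any(clades$len_min < 1e3) || any(clades$len_max > 2e6) ||
      any(clades$len_min > clades$len_max))
    stop("genome length ranges must lie within [1 kb, 2 Mb]")
  iupac_to_regex(cfg$branch_motif)  # validates the motif
  class(cfg) <- "community_config"
  cfg
}

# log-normal intron length with the configured mode
sample_intron_lengths <- function(n, mode, sdlog) {
  if (n == 0) return(integer())
  meanlog <- log(mode) + sdlog^2
  pmax(20L, as.integer(round(rlnorm(n, meanlog, sdlog))))
}

# sample the skeleton (structure, no sequence) of one gene
sample_gene_skeleton <- function(cfg) {
  exonic <- as.integer(round(rlnorm(1, log(cfg$mean_gene_len), 0.4)))
  exonic <- min(max(exonic, 300L), 3000L)
  exonic <- exonic - exonic %% 3L
  is_morph <- runif(1) < cfg$morph_fraction
  rate <- cfg$intron_rate * (if (is_morph) cfg$morph_intron_factor else 1)
  n_introns <- rpois(1, rate * exonic / 1000)
  n_introns <- min(n_introns, max(0L, (exonic - 60L) %/% 30L))
  introns <- list()
  if (n_introns > 0) {
    lens <- sample_intron_lengths(n_introns, cfg$intron_length_mode,
                                  cfg$intron_length_sdlog)
    minor <- runif(n_introns) < cfg$minor_splice_fraction
    introns <- lapply(seq_len(n_introns), function(i)
      list(length = lens[i], class = if (minor[i]) "minor" else "major",
           kind = "plain", motif = runif(1) < cfg$branch_motif_fraction))
  }
  list(exonic = exonic, is_morph = is_morph, introns = introns)
}

# can a motif of length k be planted fully inside the acceptor window
# without touching the donor dinucleotide?
motif_plantable <- function(len, window, k) {
  lo <- len + window[1]      # 0-based earliest motif start
  hi <- len + window[2] - k  # 0-based latest start fully inside the window
  lo >= 3 && hi >= lo
}

# build the oriented sequence of one intron from its skeleton entry
build_intron_seq <- function(intr, cfg, gc) {
  if (intr$kind %in% c("introner", "decoy")) return(intr$template)
  dinucs <- if (intr$class == "minor") c("AT", "AC") else c("GT", "AG")
  len <- intr$length
  if (intr$kind == "nested") {
    orf_nt <- 3L * (intr$aa + 1L) + 3L  # ATG + codons + stop
    lead <- 12L
    tail_len <- len - 4L - lead - orf_nt
    orf <- paste0("ATG", random_codons(intr$aa, gc), "TAA")
    if (intr$orf_strand == "-") orf <- revcomp(orf)
    interior <- paste0(random_dna(lead, gc), orf, random_dna(tail_len, gc))
    return(paste0(dinucs[1], interior, dinucs[2]))
  }
  interior <- random_dna(len - 4L, gc)
  if (isTRUE(intr$motif) &&
      motif_plantable(len, cfg$branch_window, nchar(cfg$branch_motif))) {
    inst <- iupac_instance(cfg$branch_motif)
    k <- nchar(inst)
    # plant so the whole motif sits inside [window] relative to the 3' end
    lo <- len + cfg$branch_window[1]      # 0-based motif start, earliest
    hi <- len + cfg$branch_window[2] - k  # latest start inside the window
    pos0 <- sample(lo:hi, 1)  # 0-based within the full intron
    ioff <- pos0 - 2L         # offset within interior (after donor)
    substr(interior, ioff + 1L, ioff + k) <- inst
  }
  paste0(dinucs[1], interior, dinucs[2])
}

# assemble one gene block; returns the genomic sequence plus exon/intron
# intervals relative to the block start
assemble_gene <- function(skel, strand, cfg, gc) {
  n_int <- length(skel$introns)
  exonic <- skel$exonic
  if (n_int > 0) {
    # choose distinct insertion points, >= 25 bp apart, away from the ends
    cand <- seq(30L, exonic - 30L, by = 1L)
    pts <- integer(0)
    for (i in seq_len(n_int)) {
      ok <- cand[vapply(cand, function(p) all(abs(p - pts) >= 25L), logical(1))]
      if (length(ok) == 0) break
      pts <- sort(c(pts, sample(ok, 1)))
    }
    n_int <- length(pts)
  } else pts <- integer(0)
  bounds <- c(0L, pts, exonic)
  exon_lens <- diff(bounds)
  exon_seqs <- vapply(exon_lens, function(l) random_dna(l, gc), character(1))
  introns <- skel$introns[seq_len(n_int)]
  intron_seqs <- vapply(introns, function(i) build_intron_seq(i, cfg, gc),
                        character(1))
  # decoy flank overrides: force the 10 bp of exon sequence on both sides
  for (i in seq_along(introns)) {
    fl <- introns[[i]]$flanks
    if (!is.null(fl)) {
      up <- exon_seqs[i]
      substr(up, nchar(up) - 9L, nchar(up)) <- fl[1]
      exon_seqs[i] <- up
      dn <- exon_seqs[i + 1]
      substr(dn, 1L, 10L) <- fl[2]
      exon_seqs[i + 1] <- dn
    }
  }
  # interleave exon/intron segments in transcript order
  segs <- character(2 * n_int + 1)
  types <- character(2 * n_int + 1)
  segs[seq(1, by = 2, length.out = n_int + 1)] <- exon_seqs
  types[seq(1, by = 2, length.out = n_int + 1)] <- "exon"
  if (n_int > 0) {
    segs[seq(2, by = 2, length.out = n_int)] <- intron_seqs
    types[seq(2, by = 2, length.out = n_int)] <- "intron"
  }
  lens <- nchar(segs)
  ends <- cumsum(lens)
  starts <- ends - lens
  block_len <- ends[length(ends)]
  block <- paste(segs, collapse = "")
  if (strand == "-") {
    block <- revcomp(block)
    new_starts <- block_len - ends
    ends <- block_len - starts
    starts <- new_starts
    # transcript order 1..k corresponds to descending genomic coordinates
  }
  list(seq = block, len = block_len,
       seg_type = types, seg_start = starts, seg_end = ends,
       introns = introns, n_introns = n_int)
}

#' Generate a synthetic mirusvirus community with truth tables
#'
#' @param config a [community_config()] object.
#' @return a list with elements `sequences` (named character vector of
#'   contigs), `bins` (bin membership), `contigs`, `hits` (best-hit
#'   table), `proteins`, `membership` (protein-cluster table),
#'   `annotations`, `ani`, `tree` (`ape::phylo` clade tree) and `truth`
#'   (genomes, genes, introns, introners, decoy pairs, nested ORFs,
#'   trans-splice pairs, contig categories, rank assignments).
#' @export
generate_community <- function(config) {
  if (!inherits(config, "community_config"))
    stop("config must be created by community_config()")
  cfg <- config
  set.seed(cfg$seed)

  genomes <- do.call(rbind, lapply(seq_len(nrow(cfg$clades)), function(i) {
    cl <- cfg$clades[i, ]
    data.frame(clade = cl$clade, len_min = cl$len_min, len_max = cl$len_max,
               gc = cl$gc, stringsAsFactors = FALSE)[rep(1, cl$n_genomes), ]
  }))
  genomes$genome_id <- sprintf("g%02d", seq_len(nrow(genomes)))
  rownames(genomes) <- NULL
  n_gen <- nrow(genomes)

  # community-level designations (fixed under the root seed)
  introner_genome <- genomes$genome_id[1]
  trans_genome <- if (cfg$trans_split) {
    idx <- which(genomes$clade == genomes$clade[min(2, n_gen)])[1]
    genomes$genome_id[min(max(idx, 2), n_gen)]
  } else NA_character_
  nested_alloc <- table(sample(genomes$genome_id, cfg$nested_orf_count,
                               replace = TRUE))

  per_genome <- vector("list", n_gen)
  for (i in seq_len(n_gen)) {
    g <- genomes[i, ]
    set.seed(derive_seed(cfg$seed, g$genome_id))
    per_genome[[i]] <- build_genome(
      g$genome_id, g$clade, c(g$len_min, g$len_max), g$gc, cfg,
      is_introner = identical(g$genome_id, introner_genome),
      is_trans = identical(g$genome_id, trans_genome),
      n_nested = if (g$genome_id %in% names(nested_alloc))
        as.integer(nested_alloc[[g$genome_id]]) else 0L)
  }

  sequences <- unlist(lapply(per_genome, `[[`, "sequences"))
  contigs <- do.call(rbind, lapply(per_genome, `[[`, "contigs"))
  genes <- do.call(rbind, lapply(per_genome, `[[`, "genes"))
  introns <- do.call(rbind, lapply(per_genome, `[[`, "introns"))
  proteins <- do.call(rbind, lapply(per_genome, `[[`, "proteins"))
  hits <- do.call(rbind, lapply(per_genome, `[[`, "hits"))
  introner_truth <- do.call(rbind, lapply(per_genome, `[[`, "introner_truth"))
  decoy_truth <- do.call(rbind, lapply(per_genome, `[[`, "decoy_truth"))
  nested_truth <- do.call(rbind, lapply(per_genome, `[[`, "nested_truth"))
  trans_truth <- do.call(rbind, lapply(per_genome, `[[`, "trans_truth"))
  genomes$length <- vapply(per_genome, function(p) sum(p$contigs$length),
                           numeric(1))
  genomes$n_genes <- vapply(per_genome, function(p) nrow(p$genes), numeric(1))

  set.seed(derive_seed(cfg$seed, "community"))

  # bins: one per genome, plus cellular contaminant contigs
  contigs$bin_id <- paste0("bin_", contigs$genome_id)
  cell_rows <- list()
  cell_hits <- list()
  cell_prot <- list()
  for (i in seq_len(n_gen)) {
    gid <- genomes$genome_id[i]
    nv <- sum(contigs$genome_id == gid)
    k <- round(cfg$contamination / (1 - cfg$contamination) * nv)
    if (k <= 0) next
    for (j in seq_len(k)) {
      cid <- paste0("bin_", gid, "_cell", j)
      len <- as.integer(round(runif(1, 3000, 30000)))
      sequences[[cid]] <- random_dna(len, 0.5)
      cat_j <- sample(c("Bacteria", "Archaea", "plastid"), 1,
                      prob = c(0.7, 0.2, 0.1))
      cell_rows[[length(cell_rows) + 1]] <- data.frame(
        contig_id = cid, genome_id = NA_character_, length = len,
        has_mcp = FALSE, bin_id = paste0("bin_", gid),
        category = cat_j, clade = NA_character_, stringsAsFactors = FALSE)
      np <- max(2L, as.integer(round(len / 1200)))
      pid <- paste0(cid, ".p", seq_len(np))
      with_hit <- runif(np) < cfg$cellular_hit_fraction
      cell_prot[[length(cell_prot) + 1]] <- data.frame(
        protein_id = pid, contig_id = cid, gene_id = NA_character_,
        stringsAsFactors = FALSE)
      if (any(with_hit)) {
        cell_hits[[length(cell_hits) + 1]] <- data.frame(
          query = pid[with_hit],
          subject = paste0(cat_j, "||cellref",
                           sample(1e5, sum(with_hit))),
          pident = runif(sum(with_hit), 40, 95),
          length = 200, mismatch = 0, gapopen = 0, qstart = 1, qend = 200,
          sstart = 1, send = 200, evalue = 1e-40,
          bitscore = runif(sum(with_hit), 90, 250),
          subject_category = cat_j, subject_clade = NA_character_,
          subject_protein = "cellref", stringsAsFactors = FALSE)
      }
    }
  }
  contigs$category <- "Mirusviricota"
  contigs$clade <- genomes$clade[match(contigs$genome_id, genomes$genome_id)]
  if (length(cell_rows) > 0)
    contigs <- rbind(contigs, do.call(rbind, cell_rows))
  if (length(cell_hits) > 0)
    hits <- rbind(hits, do.call(rbind, cell_hits))
  if (length(cell_prot) > 0)
    proteins <- rbind(proteins, do.call(rbind, cell_prot))
  hits$query_protein_id <- hits$query
  hits$query_contig_id <- sub("\\.p[0-9]+$", "", hits$query)
  bins <- data.frame(bin_id = contigs$bin_id, contig_id = contigs$contig_id,
                     stringsAsFactors = FALSE)

  # protein-cluster membership: per-clade single-copy core clusters plus
  # accessory clusters and singletons
  membership <- list()
  for (i in seq_len(n_gen)) {
    gid <- genomes$genome_id[i]
    cl <- genomes$clade[i]
    gg <- genes[genes$genome_id == gid, ]
    gene_pool <- unique(gg$gene_id)
    n_core <- cfg$sccg_per_clade
    core_ids <- sprintf("%s_core_%03d", cl, seq_len(n_core))
    present <- runif(n_core) >= cfg$sccg_missing_rate
    dup <- runif(n_core) < cfg$sccg_dup_rate
    need <- sum(present) + sum(present & dup)
    take <- sample(gene_pool, min(need, length(gene_pool)))
    rows <- list()
    k <- 1L
    for (ci in seq_len(n_core)) {
      if (!present[ci] || k > length(take)) next
      rows[[length(rows) + 1]] <- data.frame(
        genome_id = gid, gene_id = take[k], cluster_id = core_ids[ci],
        stringsAsFactors = FALSE)
      k <- k + 1L
      if (dup[ci] && k <= length(take)) {
        rows[[length(rows) + 1]] <- data.frame(
          genome_id = gid, gene_id = take[k], cluster_id = core_ids[ci],
          stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
    rest <- setdiff(gene_pool, take[seq_len(min(k - 1, length(take)))])
    if (length(rest) > 0) {
      acc <- runif(length(rest)) < 0.7
      if (any(acc)) {
        rows[[length(rows) + 1]] <- data.frame(
          genome_id = gid, gene_id = rest[acc],
          cluster_id = sprintf("%s_acc_%03d", cl,
                               sample(200L, sum(acc), replace = TRUE)),
          stringsAsFactors = FALSE)
      }
    }
    mem <- do.call(rbind, rows)
    mem$contig_id <- gg$contig_id[match(mem$gene_id, gg$gene_id)]
    membership[[i]] <- mem[, c("genome_id", "contig_id", "gene_id",
                               "cluster_id")]
  }
  membership <- do.call(rbind, membership)

  annotations <- data.frame(
    gene_id = genes$gene_id[!duplicated(genes$gene_id)],
    genome_id = genes$genome_id[!duplicated(genes$gene_id)],
    stringsAsFactors = FALSE)
  annotations$annotated <- runif(nrow(annotations)) < cfg$annotation_rate

  # ANI table: within-clade background pairs below the identity gate plus
  # planted redundant pairs
  ani_rows <- list()
  for (cl in unique(genomes$clade)) {
    ids <- genomes$genome_id[genomes$clade == cl]
    if (length(ids) < 2) next
    prs <- utils::combn(ids, 2)
    ani_rows[[length(ani_rows) + 1]] <- data.frame(
      genome_a = prs[1, ], genome_b = prs[2, ],
      ani = runif(ncol(prs), 78, 92),
      aligned_fraction = runif(ncol(prs), 0.05, 0.5),
      stringsAsFactors = FALSE)
  }
  ani <- do.call(rbind, ani_rows)
  redundant <- data.frame(genome_a = character(), genome_b = character(),
                          stringsAsFactors = FALSE)
  if (cfg$redundant_pairs > 0 && !is.null(ani) && nrow(ani) > 0) {
    pick <- sample(nrow(ani), min(cfg$redundant_pairs, nrow(ani)))
    ani$ani[pick] <- runif(length(pick), 98.2, 99.8)
    ani$aligned_fraction[pick] <- runif(length(pick), 0.3, 0.8)
    redundant <- ani[pick, c("genome_a", "genome_b")]
  }

  # planted rank structure and clade tree
  ranks <- plant_ranks(genomes, cfg)
  tree <- generate_clade_tree(ranks)

  list(
    config = cfg,
    sequences = sequences,
    bins = bins,
    contigs = contigs,
    hits = hits,
    proteins = proteins,
    membership = membership,
    annotations = annotations,
    ani = ani,
    tree = tree,
    truth = list(
      genomes = genomes[, c("genome_id", "clade", "length", "n_genes")],
      genes = genes,
      introns = introns,
      introners = introner_truth,
      decoy_pairs = decoy_truth,
      nested_orfs = nested_truth,
      trans_pairs = trans_truth,
      contig_categories = contigs[, c("contig_id", "bin_id", "category",
                                      "clade", "length", "has_mcp")],
      ranks = ranks,
      redundant_pairs = redundant
    )
  )
}

# build one genome: contigs, sequences and truth rows
build_genome <- function(genome_id, clade, len_range, gc, cfg,
                         is_introner = FALSE, is_trans = FALSE,
                         n_nested = 0L) {
  L <- round(runif(1, len_range[1], len_range[2]))
  n_contigs <- max(1L, min(sample(2:5, 1), L %/% 30000L))
  w <- runif(n_contigs, 0.5, 1.5)
  contig_targets <- pmax(cfg$min_contig * 4L, round(L * w / sum(w)))

  # sample gene skeletons for the whole genome
  n_genes_target <- max(5L, round(cfg$gene_density * L / 1000))
  skels <- lapply(seq_len(n_genes_target), function(i) sample_gene_skeleton(cfg))

  # designate special introns on the skeletons
  with_intr <- which(vapply(skels, function(s) length(s$introns) > 0,
                            logical(1)))
  needed <- (if (is_introner) cfg$introner_families * cfg$introner_copies else
    0L) + (if (is_introner) 2L * cfg$paralog_decoy_pairs else 0L) + n_nested
  if (length(with_intr) < needed) {
    # force an intron into enough intronless genes
    add <- setdiff(seq_along(skels), with_intr)[seq_len(
      min(needed - length(with_intr), n_genes_target - length(with_intr)))]
    for (i in add) {
      skels[[i]]$introns <- list(list(
        length = sample_intron_lengths(1, cfg$intron_length_mode,
                                       cfg$intron_length_sdlog),
        class = "major", kind = "plain", motif = FALSE))
    }
    with_intr <- sort(c(with_intr, add))
  }
  pool <- sample(with_intr)
  introner_map <- list()
  decoy_map <- list()
  if (is_introner) {
    for (f in seq_len(cfg$introner_families)) {
      tmpl <- paste0("GT", random_dna(cfg$introner_length - 4L, gc), "AG")
      take <- pool[seq_len(cfg$introner_copies)]
      pool <- pool[-seq_len(cfg$introner_copies)]
      for (gi in take) {
        skels[[gi]]$introns[[1]]$kind <- "introner"
        skels[[gi]]$introns[[1]]$template <- tmpl
        skels[[gi]]$introns[[1]]$length <- cfg$introner_length
        skels[[gi]]$introns[[1]]$class <- "major"
        skels[[gi]]$introns[[1]]$family <- f
      }
      introner_map[[f]] <- take
    }
    for (d in seq_len(cfg$paralog_decoy_pairs)) {
      ilen <- sample_intron_lengths(1, cfg$intron_length_mode,
                                    cfg$intron_length_sdlog)
      tmpl <- paste0("GT", random_dna(ilen - 4L, gc), "AG")
      flanks <- c(random_dna(10, gc), random_dna(10, gc))
      take <- pool[1:2]
      pool <- pool[-(1:2)]
      for (gi in take) {
        skels[[gi]]$introns[[1]]$kind <- "decoy"
        skels[[gi]]$introns[[1]]$template <- tmpl
        skels[[gi]]$introns[[1]]$length <- ilen
        skels[[gi]]$introns[[1]]$class <- "major"
        skels[[gi]]$introns[[1]]$pair <- d
        skels[[gi]]$introns[[1]]$flanks <- flanks
      }
      decoy_map[[d]] <- take
    }
  }
  if (n_nested > 0) {
    take <- pool[seq_len(min(n_nested, length(pool)))]
    for (gi in take) {
      aa <- sample(seq(cfg$nested_aa_range[1], cfg$nested_aa_range[2]), 1)
      skels[[gi]]$introns[[1]]$kind <- "nested"
      skels[[gi]]$introns[[1]]$aa <- aa
      skels[[gi]]$introns[[1]]$orf_strand <- sample(c("+", "-"), 1)
      skels[[gi]]$introns[[1]]$length <-
        as.integer(3L * (aa + 1L) + 3L + 4L + 12L + sample(20:120, 1))
      skels[[gi]]$introns[[1]]$class <- "major"
    }
  }

  # lay genes onto contigs; genes carrying planted features go first so
  # that none of them is lost when a contig reaches its target length
  special <- vapply(skels, function(s)
    length(s$introns) > 0 &&
      any(vapply(s$introns, function(i) i$kind != "plain", logical(1))),
    logical(1))
  skels <- c(skels[special], skels[!special])
  intergap_mean <- max(80, 1000 / cfg$gene_density - cfg$mean_gene_len)
  seqs <- character(n_contigs)
  contig_ids <- paste0(genome_id, "_c", seq_len(n_contigs))
  gene_rows <- list(); intron_rows <- list()
  introner_rows <- list(); decoy_rows <- list(); nested_rows <- list()
  trans_rows <- list()
  gi <- 1L; gene_n <- 1L; intron_n <- 1L
  for (ci in seq_len(n_contigs)) {
    segs <- character(0)
    cursor <- 0L
    if (is_trans && ci == 1L) {
      # reserved region: fragment A .. GT spacer AG .. fragment B
      lead <- random_dna(3000, gc)
      segs <- c(segs, lead); cursor <- cursor + 3000L
      lenA <- 1200L; lenB <- 900L
      a1 <- cursor; a2 <- a1 + lenA
      idA <- sprintf("%s_g%04d", genome_id, gene_n); gene_n <- gene_n + 1L
      segs <- c(segs, random_dna(lenA, gc)); cursor <- a2
      sep <- cfg$trans_separation
      spacer <- paste0("GT", random_dna(sep - 4L, gc), "AG")
      segs <- c(segs, spacer); cursor <- cursor + sep
      b1 <- cursor; b2 <- b1 + lenB
      idB <- sprintf("%s_g%04d", genome_id, gene_n); gene_n <- gene_n + 1L
      segs <- c(segs, random_dna(lenB, gc)); cursor <- b2
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = c(idA, idB), genome_id = genome_id,
        contig_id = contig_ids[ci], strand = "+",
        start = c(a1, b1), end = c(a2, b2), exon_rank = 1L,
        is_morph = TRUE, gene_class = "terminase_fragment",
        stringsAsFactors = FALSE)
      trans_rows[[1]] <- data.frame(
        genome_id = genome_id, contig_id = contig_ids[ci],
        fragment_a = idA, fragment_b = idB,
        donor_pos = a2, acceptor_pos = b1, donor_strand = "+",
        acceptor_strand = "+", separation = b1 - a2,
        stringsAsFactors = FALSE)
    }
    while (gi <= length(skels) && cursor < contig_targets[ci]) {
      gap <- as.integer(60L + round(rexp(1, 1 / intergap_mean)))
      strand <- sample(c("+", "-"), 1)
      built <- assemble_gene(skels[[gi]], strand, cfg, gc)
      if (cursor + gap + built$len > contig_targets[ci] + 20000L) break
      segs <- c(segs, random_dna(gap, gc), built$seq)
      gstart <- cursor + gap
      cursor <- gstart + built$len
      id <- sprintf("%s_g%04d", genome_id, gene_n)
      ex <- built$seg_type == "exon"
      ord <- order(built$seg_start[ex])
      gene_rows[[length(gene_rows) + 1]] <- data.frame(
        gene_id = id, genome_id = genome_id, contig_id = contig_ids[ci],
        strand = strand, start = gstart + built$seg_start[ex][ord],
        end = gstart + built$seg_end[ex][ord],
        exon_rank = seq_len(sum(ex)),
        is_morph = skels[[gi]]$is_morph, gene_class = "other",
        stringsAsFactors = FALSE)
      if (built$n_introns > 0) {
        iv <- which(built$seg_type == "intron")
        # seg order follows transcript order; genomic coords already mapped
        for (k in seq_along(iv)) {
          intr <- built$introns[[k]]
          iid <- sprintf("%s_i%05d", genome_id, intron_n)
          intron_n <- intron_n + 1L
          intron_rows[[length(intron_rows) + 1]] <- data.frame(
            intron_id = iid, gene_id = id, genome_id = genome_id,
            contig_id = contig_ids[ci], strand = strand,
            start = gstart + built$seg_start[iv[k]],
            end = gstart + built$seg_end[iv[k]],
            length = built$seg_end[iv[k]] - built$seg_start[iv[k]],
            class = intr$class, kind = intr$kind,
            has_motif = isTRUE(intr$motif) && intr$kind == "plain" &&
              motif_plantable(built$seg_end[iv[k]] - built$seg_start[iv[k]],
                              cfg$branch_window, nchar(cfg$branch_motif)),
            stringsAsFactors = FALSE)
          if (intr$kind == "introner")
            introner_rows[[length(introner_rows) + 1]] <- data.frame(
              intron_id = iid, genome_id = genome_id,
              family = intr$family, stringsAsFactors = FALSE)
          if (intr$kind == "decoy")
            decoy_rows[[length(decoy_rows) + 1]] <- data.frame(
              intron_id = iid, genome_id = genome_id, pair = intr$pair,
              stringsAsFactors = FALSE)
          if (intr$kind == "nested")
            nested_rows[[length(nested_rows) + 1]] <- data.frame(
              intron_id = iid, genome_id = genome_id, aa_length = intr$aa,
              orf_strand = intr$orf_strand, stringsAsFactors = FALSE)
        }
      }
      gi <- gi + 1L
      gene_n <- gene_n + 1L
    }
    segs <- c(segs, random_dna(200L, gc))
    seqs[ci] <- paste(segs, collapse = "")
  }
  names(seqs) <- contig_ids
  genes <- do.call(rbind, gene_rows)
  introns <- if (length(intron_rows) > 0) do.call(rbind, intron_rows) else
    empty_intron_truth()

  contigs <- data.frame(contig_id = contig_ids, genome_id = genome_id,
                        length = nchar(seqs), stringsAsFactors = FALSE)
  contigs$has_mcp <- contigs$length == max(contigs$length)
  contigs$has_mcp[duplicated(contigs$has_mcp) & contigs$has_mcp] <- FALSE

  # proteins and reference best hits
  prot_rows <- list(); hit_rows <- list()
  for (ci in seq_len(n_contigs)) {
    cg <- genes[genes$contig_id == contig_ids[ci], ]
    ids <- unique(cg$gene_id)
    if (length(ids) == 0) next
    pid <- paste0(contig_ids[ci], ".p", seq_along(ids))
    prot_rows[[ci]] <- data.frame(protein_id = pid,
                                  contig_id = contig_ids[ci], gene_id = ids,
                                  stringsAsFactors = FALSE)
    with_hit <- runif(length(ids)) < cfg$hit_fraction
    if (contigs$has_mcp[ci] && !with_hit[1]) with_hit[1] <- TRUE
    if (any(with_hit)) {
      subj_prot <- paste0("ref", sample(1e6, sum(with_hit)))
      if (contigs$has_mcp[ci]) subj_prot[1] <- "MCP"
      hit_rows[[ci]] <- data.frame(
        query = pid[with_hit],
        subject = paste("Mirusviricota", clade, subj_prot, sep = "|"),
        pident = runif(sum(with_hit), 35, 90),
        length = 250, mismatch = 0, gapopen = 0, qstart = 1, qend = 250,
        sstart = 1, send = 250, evalue = 1e-50,
        bitscore = runif(sum(with_hit), 80, 300),
        subject_category = "Mirusviricota", subject_clade = clade,
        subject_protein = subj_prot, stringsAsFactors = FALSE)
    }
  }

  list(sequences = as.list(seqs), contigs = contigs, genes = genes,
       introns = introns,
       proteins = do.call(rbind, prot_rows),
       hits = do.call(rbind, hit_rows),
       introner_truth = if (length(introner_rows) > 0)
         do.call(rbind, introner_rows) else NULL,
       decoy_truth = if (length(decoy_rows) > 0)
         do.call(rbind, decoy_rows) else NULL,
       nested_truth = if (length(nested_rows) > 0)
         do.call(rbind, nested_rows) else NULL,
       trans_truth = if (length(trans_rows) > 0)
         do.call(rbind, trans_rows) else NULL)
}

empty_intron_truth <- function() {
  data.frame(intron_id = character(), gene_id = character(),
             genome_id = character(), contig_id = character(),
             strand = character(), start = numeric(), end = numeric(),
             length = numeric(), class = character(), kind = character(),
             has_motif = logical(), stringsAsFactors = FALSE)
}

# assign planted taxonomic ranks: orders = clades, families within,
# with some genomes designated as single-genome families
plant_ranks <- function(genomes, cfg) {
  ranks <- data.frame(genome_id = genomes$genome_id, order = genomes$clade,
                      family = NA_character_, singleton = FALSE,
                      stringsAsFactors = FALSE)
  # designate singleton-family genomes (last genome of the largest clades)
  singles <- character(0)
  if (cfg$singleton_families > 0) {
    by_clade <- split(ranks$genome_id, ranks$order)
    big <- names(sort(vapply(by_clade, length, integer(1)),
                      decreasing = TRUE))
    for (i in seq_len(min(cfg$singleton_families, length(big)))) {
      ids <- by_clade[[big[i]]]
      singles <- c(singles, ids[length(ids)])
    }
  }
  ranks$singleton <- ranks$genome_id %in% singles
  for (cl in unique(ranks$order)) {
    idx <- which(ranks$order == cl & !ranks$singleton)
    nf <- max(1L, min(cfg$families_per_clade, length(idx) %/% 2L))
    ranks$family[idx] <- sprintf("%s_f%d", cl,
                                 rep_len(seq_len(nf), length(idx)))
  }
  ranks$family[ranks$singleton] <-
    paste0("single_", ranks$genome_id[ranks$singleton])
  ranks
}

#' Build a clade tree with planted order and family depth structure
#'
#' Constructs a rooted tree in which clades (orders) branch off close to
#' the root and families at intermediate depth, so that RED-based rank
#' delineation at the 0.22/0.65 thresholds recovers the planted partition.
#' Singleton-family genomes hang on long branches directly below their
#' order node.
#'
#' @param ranks data frame with `genome_id`, `order`, `family`,
#'   `singleton` columns (as in the community truth tables).
#' @param stem,family_depth,leaf_depth,singleton_depth branch lengths.
#' @param jitter multiplicative branch-length jitter (fraction).
#' @return an `ape::phylo` rooted tree whose tips are genome ids.
#' @export
generate_clade_tree <- function(ranks, stem = 0.12, family_depth = 0.5,
                                leaf_depth = 0.38, singleton_depth = 0.88,
                                jitter = 0.04) {
  j <- function(x) x * runif(length(x), 1 - jitter, 1 + jitter)
  order_parts <- vapply(unique(ranks$order), function(ord) {
    sub <- ranks[ranks$order == ord, ]
    fam_parts <- vapply(unique(sub$family[!sub$singleton]), function(fm) {
      tips <- sub$genome_id[sub$family == fm & !sub$singleton]
      if (length(tips) == 1)
        return(sprintf("%s:%.6f", tips, j(family_depth + leaf_depth)))
      sprintf("(%s):%.6f",
              paste(sprintf("%s:%.6f", tips, j(rep(leaf_depth,
                                                   length(tips)))),
                    collapse = ","),
              j(family_depth))
    }, character(1))
    single_parts <- sprintf("%s:%.6f", sub$genome_id[sub$singleton],
                            j(rep(singleton_depth, sum(sub$singleton))))
    sprintf("(%s):%.6f", paste(c(fam_parts, single_parts), collapse = ","),
            j(stem))
  }, character(1))
  nwk <- sprintf("(%s);", paste(order_parts, collapse = ","))
  ape::read.tree(text = nwk)
}

#' Corrupt truth gene models into prediction sets with planted errors
#'
#' Emulates the two failure modes of intron-aware gene predictors: fusing
#' two adjacent intronless genes with a spurious intron, and splitting an
#' intronless gene into a two-exon model with a very short first exon. The
#' intronless ORF-caller set contains the correct single-exon genes needed
#' to repair both.
#'
#' @param community output of [generate_community()] (or a list with a
#'   `truth$genes` exon table).
#' @param error_rates named vector `c(fusion = , spurious = )`; rates are
#'   the fraction of eligible cases corrupted.
#' @return list with `intron_aware` and `orf` exon tables and a
#'   `corruptions` ledger (`type`, `corrupted_id`, `original_ids`).
#' @export
generate_predictions <- function(community,
                                 error_rates = community$config$
                                   prediction_error_rates) {
  genes <- community$truth$genes
  fusion_rate <- unname(error_rates[["fusion"]])
  spurious_rate <- unname(error_rates[["spurious"]])
  n_ex <- table(genes$gene_id)
  single <- names(n_ex)[n_ex == 1]
  sing <- genes[genes$gene_id %in% single, ]
  sing$len <- sing$end - sing$start

  used <- character(0)
  ledger <- list()
  ia_rows <- list()

  # fusion corruption: genomically adjacent single-exon genes (no other
  # gene in between), same contig and strand
  fp_all <- model_footprints(genes[, c("gene_id", "contig_id", "strand",
                                       "start", "end")])
  if (fusion_rate > 0) {
    for (ctg in unique(sing$contig_id)) {
      cs <- fp_all[fp_all$contig_id == ctg, ]
      cs <- cs[order(cs$start), ]
      if (nrow(cs) < 2) next
      for (i in seq_len(nrow(cs) - 1)) {
        a <- cs[i, ]; b <- cs[i + 1, ]
        if (a$n_exons != 1 || b$n_exons != 1) next
        a$len <- a$end - a$start; b$len <- b$end - b$start
        if (a$gene_id %in% used || b$gene_id %in% used) next
        if (a$strand != b$strand) next
        if (a$len <= 300 || b$len <= 300) next
        if (b$start - a$end < 4) next
        if (runif(1) >= fusion_rate) next
        fid <- paste0("fused_", a$gene_id, "_", b$gene_id)
        ia_rows[[length(ia_rows) + 1]] <- data.frame(
          gene_id = fid, contig_id = ctg, strand = a$strand,
          start = c(a$start, b$start), end = c(a$end, b$end),
          source = "intron_aware", stringsAsFactors = FALSE)
        ledger[[length(ledger) + 1]] <- data.frame(
          type = "fusion", corrupted_id = fid,
          original_ids = paste(a$gene_id, b$gene_id, sep = ","),
          stringsAsFactors = FALSE)
        used <- c(used, a$gene_id, b$gene_id)
      }
    }
  }

  # spurious short-exon corruption on remaining single-exon genes
  if (spurious_rate > 0) {
    elig <- sing[!(sing$gene_id %in% used) & sing$len >= 400, ]
    pick <- elig[runif(nrow(elig)) < spurious_rate, , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      g <- pick[i, ]
      d <- 12L; gap <- 18L
      sid <- paste0("split_", g$gene_id)
      ia_rows[[length(ia_rows) + 1]] <- data.frame(
        gene_id = sid, contig_id = g$contig_id, strand = g$strand,
        start = c(g$start, g$start + d + gap), end = c(g$start + d, g$end),
        source = "intron_aware", stringsAsFactors = FALSE)
      ledger[[length(ledger) + 1]] <- data.frame(
        type = "spurious_exon", corrupted_id = sid,
        original_ids = g$gene_id, stringsAsFactors = FALSE)
      used <- c(used, g$gene_id)
    }
  }

  keep <- genes[!(genes$gene_id %in% used), c("gene_id", "contig_id",
                                              "strand", "start", "end")]
  keep$source <- "intron_aware"
  ia <- rbind(keep, do.call(rbind, ia_rows))
  ia <- ia[order(ia$contig_id, ia$gene_id, ia$start), ]
  rownames(ia) <- NULL

  orf <- sing[, c("gene_id", "contig_id", "strand", "start", "end")]
  orf$gene_id <- paste0("orf_", orf$gene_id)
  orf$source <- "orf"
  rownames(orf) <- NULL

  corruptions <- if (length(ledger) > 0) do.call(rbind, ledger) else
    data.frame(type = character(), corrupted_id = character(),
               original_ids = character(), stringsAsFactors = FALSE)
  list(intron_aware = ia, orf = orf, corruptions = corruptions)
}

#' Generate RNA junction evidence from the community truth
#'
#' One junction row per true intron and per trans-splice pair, with read
#' counts drawn as Poisson around `coverage_mean`, plus a configurable
#' fraction of decoy junctions with sub-threshold counts. Rows with zero
#' reads are dropped.
#'
#' @param community output of [generate_community()].
#' @param coverage_mean mean read support of true junctions.
#' @param decoy_fraction decoy junctions as a fraction of true junctions.
#' @param decoy_count_max maximum read count of a decoy (default 9, i.e.
#'   below the evidence threshold of ten reads).
#' @return junction evidence data frame (with a `truth` column labelling
#'   `intron`, `trans` or `decoy` rows).
#' @export
generate_junctions <- function(community, coverage_mean = 30,
                               decoy_fraction = 0.2, decoy_count_max = 9L) {
  introns <- community$truth$introns
  rows <- list()
  if (nrow(introns) > 0) {
    donor <- ifelse(introns$strand == "+", introns$start, introns$end)
    acceptor <- ifelse(introns$strand == "+", introns$end, introns$start)
    rows[[1]] <- data.frame(
      contig_id = introns$contig_id, donor_pos = donor,
      acceptor_pos = acceptor, donor_strand = introns$strand,
      acceptor_strand = introns$strand,
      read_count = rpois(nrow(introns), coverage_mean),
      truth = "intron", stringsAsFactors = FALSE)
  }
  tp <- community$truth$trans_pairs
  if (!is.null(tp) && nrow(tp) > 0) {
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = tp$contig_id, donor_pos = tp$donor_pos,
      acceptor_pos = tp$acceptor_pos, donor_strand = tp$donor_strand,
      acceptor_strand = tp$acceptor_strand,
      read_count = rpois(nrow(tp), coverage_mean), truth = "trans",
      stringsAsFactors = FALSE)
  }
  n_true <- sum(vapply(rows, nrow, integer(1)))
  n_decoy <- round(decoy_fraction * n_true)
  if (n_decoy > 0) {
    viral <- community$contigs[!is.na(community$contigs$genome_id), ]
    pick <- viral[sample(nrow(viral), n_decoy, replace = TRUE), ]
    dpos <- vapply(pick$length, function(l)
      round(runif(1, 100, max(200, l - 600))), numeric(1))
    sep <- round(runif(n_decoy, 50, 500))
    taken <- if (length(rows) > 0)
      paste(do.call(rbind, rows)$contig_id, do.call(rbind, rows)$donor_pos)
    else character(0)
    keep <- !(paste(pick$contig_id, dpos) %in% taken)
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = pick$contig_id[keep], donor_pos = dpos[keep],
      acceptor_pos = (dpos + sep)[keep], donor_strand = "+",
      acceptor_strand = "+",
      read_count = sample(decoy_count_max, sum(keep), replace = TRUE),
      truth = "decoy", stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(contig_id = character(), donor_pos = numeric(),
               acceptor_pos = numeric(), donor_strand = character(),
               acceptor_strand = character(), read_count = numeric(),
               truth = character(), stringsAsFactors = FALSE)
  out <- out[out$read_count > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subsample genomes to known retained fractions
#'
#' Used for completion-recovery experiments: each gene of each genome is
#' retained independently with the genome's target probability, and the
#' realized retained fraction (over all genes of the genome) is recorded
#' as the truth against which marker-based completion estimates are
#' compared.
#'
#' @param membership protein-cluster membership table (`genome_id`,
#'   `contig_id`, `gene_id`, `cluster_id`).
#' @param genes data frame with `genome_id` and `gene_id` listing every
#'   gene of every genome (the denominator of the realized fraction).
#' @param fractions named vector of target retention probabilities per
#'   genome.
#' @return list with `membership` (subsampled) and `truth` (data frame
#'   `genome_id`, `target_fraction`, `retained_fraction`).
#' @export
subsample_genomes <- function(membership, genes, fractions) {
  truth <- list()
  kept_rows <- list()
  for (gid in names(fractions)) {
    f <- fractions[[gid]]
    gg <- unique(genes$gene_id[genes$genome_id == gid])
    keep <- gg[runif(length(gg)) < f]
    realized <- length(keep) / length(gg)
    mem <- membership[membership$genome_id == gid &
                        membership$gene_id %in% keep, , drop = FALSE]
    kept_rows[[gid]] <- mem
    truth[[gid]] <- data.frame(genome_id = gid, target_fraction = f,
                               retained_fraction = realized,
                               stringsAsFactors = FALSE)
  }
  list(membership = do.call(rbind, kept_rows),
       truth = do.call(rbind, truth))
}

#' Write a generated community to disk
#'
#' Emits contig FASTA, bin/contig/hit/junction/ANI/membership TSV tables
#' and the clade tree in newick format, all parseable by the package's
#' readers.
#'
#' @param community output of [generate_community()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(community$sequences, file.path(dir, "contigs.fasta"))
  write.table(community$bins, file.path(dir, "bins.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(community$contigs, file.path(dir, "contigs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_hits(community$hits, file.path(dir, "hits.tsv"))
  write_clusters(community$membership, file.path(dir, "membership.tsv"))
  write_ani(community$ani, file.path(dir, "ani.tsv"))
  write_tree(community$tree, file.path(dir, "clade_tree.nwk"))
  truth_models <- community$truth$genes
  truth_models$source <- "truth"
  write_gff3(models_to_features(truth_models[, c("gene_id", "contig_id",
                                                 "strand", "start", "end")]),
             file.path(dir, "genes_truth.gff3"))
  invisible(dir)
}
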