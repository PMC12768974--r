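#' Pipeline run configuration
#'
#' Bundles the seed, stage toggles, community-generator overrides and all
#' decision thresholds. The defaults encode the reference procedure
#' (25%/50% contig assignment, 50-650 kb MAGs, sccg vetting at 0.7-1.5
#' and 70%, quality 50 / redundancy 25, ANI 98 with 25% alignment,
#' 300 bp / 100 aa nested-gene gates, 10-read junction support, RED
#' 0.22/0.65), so a configuration with no overrides runs the canonical
#' decision layer.
#'
#' @param seed integer seed driving every stage.
#' @param community named list of [community_config()] overrides.
#' @param stages character vector of stages to run (in dependency
#'   order); later stages require earlier ones.
#' @param thresholds named list of threshold overrides.
#' @return a `run_config` list.
#' @export
run_config <- function(seed = 1L, community = list(),
                       stages = c("simulate", "bin", "score", "derep",
                                  "genes", "introns", "tax"),
                       thresholds = list()) {
  defaults <- list(
    category_min_fraction = 0.25, clade_min_fraction = 0.50,
    mag_min_len = 50e3, mag_max_len = 650e3, min_contig = 2500,
    sccg_min_clade = 10, sccg_single_fraction = 0.50,
    sccg_avg_range = c(0.7, 1.5), sccg_single_min = 0.70,
    min_quality = 50, max_redundancy = 25,
    ani_max = 98, min_aligned_fraction = 0.25,
    min_exon_len = 300, overlap_min = 0.95, short_exon_fraction = 0.05,
    min_reads = 10, min_separation = 1000,
    nested_min_intron = 300, nested_min_aa = 100,
    introner_evalue = 1e-5,
    order_max = 0.22, family_max = 0.65)
  unknown <- setdiff(names(thresholds), names(defaults))
  if (length(unknown) > 0)
    stop("unknown threshold(s): ", paste(unknown, collapse = ", "))
  defaults[names(thresholds)] <- thresholds
  known_stages <- c("simulate", "bin", "score", "derep", "genes",
                    "introns", "tax")
  if (!all(stages %in% known_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, known_stages), collapse = ", "))
  structure(list(seed = as.integer(seed), community = community,
                 stages = stages, thresholds = defaults),
            class = "run_config")
}

#' Run the full pipeline on a synthetic community
#'
#' Executes simulate, bin, score, dereplicate, gene-model arbitration,
#' intron analytics and RED taxonomy in dependency order, and returns
#' all stage outputs plus a run manifest with per-stage record counts.
#' The same configuration and seed reproduce the run exactly.
#'
#' @param config a [run_config()] object.
#' @param out_dir optional directory; when given, community files and the
#'   manifest are written there.
#' @return named list of stage outputs and `manifest`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  if (!inherits(config, "run_config"))
    stop("config must be created by run_config()")
  th <- config$thresholds
  stages <- config$stages
  res <- list(config = config)
  counts <- list()

  if (!"simulate" %in% stages)
    stop("the pipeline runs on generated data: enable the simulate stage")
  ccfg <- do.call(community_config,
                  c(list(seed = config$seed), config$community))
  comm <- generate_community(ccfg)
  set.seed(derive_seed(config$seed, "predictions"))
  preds <- generate_predictions(comm)
  set.seed(derive_seed(config$seed, "junctions"))
  junctions <- generate_junctions(comm)
  res$community <- comm
  res$predictions <- preds
  res$junctions <- junctions
  counts$n_genomes <- nrow(comm$truth$genomes)
  counts$n_contigs <- nrow(comm$contigs)
  counts$n_genes <- length(unique(comm$truth$genes$gene_id))
  counts$n_introns_truth <- nrow(comm$truth$introns)

  contig_lengths <- vapply(comm$sequences, nchar, integer(1))

  if ("bin" %in% stages) {
    assignments <- assign_contigs(
      comm$hits, comm$proteins,
      min_fraction = th$category_min_fraction,
      clade_min_fraction = th$clade_min_fraction)
    built <- build_mags(comm$bins, assignments, contig_lengths,
                        min_len = th$mag_min_len, max_len = th$mag_max_len,
                        min_contig = th$min_contig)
    res$assignments <- assignments
    res$mags <- built
    counts$n_mags <- nrow(built$mags)
  }

  if ("score" %in% stages && !is.null(res$mags)) {
    members <- res$mags$members
    # per-MAG membership table (MAGs take the role of genomes)
    mem <- comm$membership[comm$membership$contig_id %in%
                             members$contig_id, , drop = FALSE]
    mem$genome_id <- members$mag_id[match(mem$contig_id,
                                          members$contig_id)]
    sccg_sets <- list()
    for (cl in unique(res$mags$mags$clade)) {
      ids <- res$mags$mags$mag_id[res$mags$mags$clade == cl]
      ds <- withCallingHandlers(
        derive_sccg(mem, ids, clade = cl,
                    min_clade_size = th$sccg_min_clade,
                    min_single_fraction = th$sccg_single_fraction),
        warning = function(w) invokeRestart("muffleWarning"))
      if (length(ds$clusters) > 0) {
        keep <- filter_sccg_models(
          ds$counts[, ds$clusters, drop = FALSE],
          avg_range = th$sccg_avg_range,
          single_fraction_min = th$sccg_single_min)
        sccg_sets[[cl]] <- keep
      }
    }
    gtab <- data.frame(genome_id = res$mags$mags$mag_id,
                       clade = res$mags$mags$clade,
                       stringsAsFactors = FALSE)
    scores <- score_genomes(mem, gtab, sccg_sets)
    res$scores <- scores
    res$kept <- final_filters(scores, min_quality = th$min_quality,
                              max_redundancy = th$max_redundancy)
    counts$n_scored <- sum(scores$scored)
    counts$n_kept <- nrow(res$kept)
  }

  if ("derep" %in% stages && !is.null(res$kept)) {
    # MAG-level ANI pairs derive from the genome-level table via the
    # bin <-> genome correspondence
    mags <- res$mags$mags[res$mags$mags$mag_id %in% res$kept$genome_id, ,
                          drop = FALSE]
    genome_of <- sub("^bin_", "", mags$bin_id)
    map <- setNames(mags$mag_id, genome_of)
    ani <- comm$ani[comm$ani$genome_a %in% names(map) &
                      comm$ani$genome_b %in% names(map), , drop = FALSE]
    ani$genome_a <- unname(map[ani$genome_a])
    ani$genome_b <- unname(map[ani$genome_b])
    gdf <- data.frame(genome_id = mags$mag_id,
                      length = mags$total_length,
                      quality = res$kept$quality[match(mags$mag_id,
                                                       res$kept$genome_id)],
                      stringsAsFactors = FALSE)
    res$representatives <- dereplicate(
      gdf, ani, ani_max = th$ani_max,
      min_aligned_fraction = th$min_aligned_fraction)
    counts$n_representatives <- nrow(res$representatives)
  }

  if ("genes" %in% stages) {
    merged <- merge_predictions(preds$intron_aware, preds$orf,
                                min_exon_len = th$min_exon_len,
                                overlap_min = th$overlap_min,
                                short_exon_fraction = th$short_exon_fraction)
    res$merged <- merged
    res$introns <- extract_introns(merged$models, comm$sequences)
    counts$n_corrections <- nrow(merged$ledger)
    counts$n_introns <- nrow(res$introns)
  }

  if ("introns" %in% stages && !is.null(res$introns)) {
    introns <- res$introns
    introns$genome_id <- comm$contigs$genome_id[match(introns$contig_id,
                                                      comm$contigs$contig_id)]
    truth_genes <- comm$truth$genes
    morph_ids <- unique(truth_genes$gene_id[truth_genes$is_morph])
    model_label <- sub("^orf_", "", res$merged$models$gene_id)
    morph_models <- unique(res$merged$models$gene_id[model_label %in%
                                                       morph_ids])
    intr2 <- introns
    intr2$gene_id_base <- sub("^orf_", "", intr2$gene_id)
    res$intron_stats <- list(
      density = intron_density(res$merged$models, introns),
      enrichment = enrichment_ratio(res$merged$models, introns,
                                    morph_models),
      motif = motif_fraction(introns, comm$config$branch_motif),
      length_mode = if (nrow(introns) >= 10) {
        d <- density(introns$length)
        d$x[which.max(d$y)]
      } else NA_real_,
      major_fraction = mean(introns$splice_class == "major"))
    res$introners <- detect_introners(introns,
                                      evalue_max = th$introner_evalue)
    res$nested <- find_nested_orfs(introns,
                                   min_intron = th$nested_min_intron,
                                   min_aa = th$nested_min_aa)
    res$trans <- detect_trans_splice(junctions, res$merged$models,
                                     comm$sequences,
                                     min_reads = th$min_reads,
                                     min_separation = th$min_separation)
    counts$n_introner_members <- nrow(res$introners)
    counts$n_nested <- nrow(res$nested)
    counts$n_trans <- nrow(res$trans)
  }

  if ("tax" %in% stages) {
    # root over the major deep-branching positions: the basal edges
    nt <- ape::Ntip(comm$tree)
    basal <- comm$tree$edge[comm$tree$edge[, 1] == nt + 1L, 2]
    basal <- basal[basal > nt]
    red <- average_red(comm$tree, candidate_roots = basal)
    res$red <- red
    res$ranks <- delineate_ranks(comm$tree, red,
                                 order_max = th$order_max,
                                 family_max = th$family_max)
    counts$n_orders <- length(unique(res$ranks$order))
    counts$n_families <- length(unique(res$ranks$family))
  }

  res$manifest <- list(
    package = "mirusmine",
    version = as.character(utils::packageVersion("mirusmine")),
    seed = config$seed,
    stages = stages,
    thresholds = th,
    counts = counts)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_community(comm, file.path(out_dir, "community"))
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

#' Do two labelings induce the same partition?
#'
#' Compares two labelings of the same items as set partitions (label
#' names are ignored).
#'
#' @param labels_a,labels_b named vectors (names = items) or data frames
#'   with `genome_id` and a label column.
#' @return logical scalar.
#' @export
same_partition <- function(labels_a, labels_b) {
  items <- sort(names(labels_a))
  if (!identical(items, sort(names(labels_b)))) return(FALSE)
  pa <- lapply(split(names(labels_a), unname(labels_a)), sort)
  pb <- lapply(split(names(labels_b), unname(labels_b)), sort)
  setequal(lapply(pa, paste, collapse = "|"),
           lapply(pb, paste, collapse = "|"))
}
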