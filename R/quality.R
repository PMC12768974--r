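#' Collapse cluster occurrences to per-contig counts
#'
#' Multiple occurrences of a cluster on the same contig are counted once,
#' to absorb intron-driven gene fragmentation. Returns, for one genome,
#' the collapsed copy count of every cluster in `cluster_ids`.
#'
#' @param membership membership rows of one genome (`contig_id`,
#'   `cluster_id`).
#' @param cluster_ids clusters to count (absent clusters get 0).
#' @return named integer vector of collapsed copy counts.
#' @export
collapse_copy_counts <- function(membership, cluster_ids) {
  counts <- setNames(integer(length(cluster_ids)), cluster_ids)
  if (nrow(membership) > 0) {
    uniq <- unique(membership[, c("contig_id", "cluster_id")])
    tab <- table(uniq$cluster_id)
    hit <- intersect(names(tab), cluster_ids)
    counts[hit] <- as.integer(tab[hit])
  }
  counts
}

#' Derive single-copy core gene (sccg) clusters for a clade
#'
#' A cluster is an sccg when it occurs in exactly one (collapsed) copy in
#' at least `min_single_fraction` of the clade's genomes. Clades with
#' fewer than `min_clade_size` genomes yield an empty set with a warning.
#'
#' @param membership protein-cluster membership (`genome_id`, `contig_id`,
#'   `gene_id`, `cluster_id`).
#' @param genome_ids genomes of the clade.
#' @param clade clade label attached to the result.
#' @param min_clade_size minimum genomes per clade (default 10).
#' @param min_single_fraction minimum single-copy fraction (default 0.50,
#'   inclusive).
#' @return list with `clade`, `clusters` (character vector of sccg ids)
#'   and `counts` (genome x cluster collapsed count matrix).
#' @export
derive_sccg <- function(membership, genome_ids, clade = NA_character_,
                        min_clade_size = 10, min_single_fraction = 0.50) {
  if (length(genome_ids) < min_clade_size) {
    warning("clade ", clade, " has fewer than ", min_clade_size,
            " genomes; no sccg derived")
    return(list(clade = clade, clusters = character(0),
                counts = matrix(0L, nrow = length(genome_ids), ncol = 0,
                                dimnames = list(genome_ids, NULL))))
  }
  mem <- membership[membership$genome_id %in% genome_ids, , drop = FALSE]
  clusters <- sort(unique(mem$cluster_id))
  counts <- t(vapply(genome_ids, function(g)
    collapse_copy_counts(mem[mem$genome_id == g, , drop = FALSE], clusters),
    integer(length(clusters))))
  if (length(clusters) == 1)
    counts <- matrix(counts, ncol = 1, dimnames = list(genome_ids, clusters))
  single_frac <- colMeans(counts == 1L)
  list(clade = clade, clusters = clusters[single_frac >= min_single_fraction],
       counts = counts)
}

#' Filter sccg models by their hit behaviour across genomes
#'
#' Mirrors the profile-model vetting step: an sccg model is retained only
#' if its mean (collapsed) hit count across the clade's genomes lies in
#' `avg_range` and it yields exactly one hit in at least
#' `single_fraction_min` of the genomes.
#'
#' @param counts genome x sccg matrix of collapsed hit counts.
#' @param avg_range allowed range of the mean count (default `c(0.7,
#'   1.5)`, inclusive).
#' @param single_fraction_min minimum fraction of genomes with exactly one
#'   hit (default 0.70, inclusive).
#' @return character vector of retained sccg ids.
#' @export
filter_sccg_models <- function(counts, avg_range = c(0.7, 1.5),
                               single_fraction_min = 0.70) {
  if (ncol(counts) == 0) return(character(0))
  means <- colMeans(counts)
  singles <- colMeans(counts == 1L)
  keep <- means >= avg_range[1] & means <= avg_range[2] &
    singles >= single_fraction_min
  colnames(counts)[keep]
}

#' Completion, redundancy and quality of one genome
#'
#' Completion is the percentage of the clade's sccg present at least
#' once (collapsed counts); redundancy the percentage present at least
#' twice; quality is completion minus redundancy.
#'
#' @param hit_counts named (or plain) integer vector of collapsed hit
#'   counts, one element per sccg of the genome's clade.
#' @return named numeric vector `c(completion, redundancy, quality)` in
#'   percent.
#' @export
score_genome <- function(hit_counts) {
  if (length(hit_counts) == 0)
    stop("empty sccg set: genome cannot be scored")
  completion <- 100 * mean(hit_counts >= 1)
  redundancy <- 100 * mean(hit_counts >= 2)
  c(completion = completion, redundancy = redundancy,
    quality = completion - redundancy)
}

#' Score a set of genomes against per-clade sccg collections
#'
#' @param membership protein-cluster membership table.
#' @param genomes data frame `genome_id`, `clade`.
#' @param sccg_sets named list (by clade) of sccg cluster id vectors;
#'   clades absent from the list yield unscored genomes.
#' @return data frame `genome_id`, `clade`, `completion`, `redundancy`,
#'   `quality`, `scored`.
#' @export
score_genomes <- function(membership, genomes, sccg_sets) {
  out <- lapply(seq_len(nrow(genomes)), function(i) {
    gid <- genomes$genome_id[i]
    cl <- genomes$clade[i]
    sccg <- if (!is.na(cl) && cl %in% names(sccg_sets)) sccg_sets[[cl]]
    else character(0)
    if (length(sccg) == 0)
      return(data.frame(genome_id = gid, clade = cl, completion = NA_real_,
                        redundancy = NA_real_, quality = NA_real_,
                        scored = FALSE, stringsAsFactors = FALSE))
    mem <- membership[membership$genome_id == gid, , drop = FALSE]
    s <- score_genome(collapse_copy_counts(mem, sccg))
    data.frame(genome_id = gid, clade = cl, completion = s[["completion"]],
               redundancy = s[["redundancy"]], quality = s[["quality"]],
               scored = TRUE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Final quality filters on scored MAGs
#'
#' Scored MAGs with quality below `min_quality` or redundancy above
#' `max_redundancy` are removed (strict bounds: quality exactly at the
#' minimum and redundancy exactly at the maximum are kept). Unscored MAGs
#' pass with an `unscored` flag.
#'
#' @param scores data frame with `quality`, `redundancy` and `scored`
#'   columns (as from [score_genomes()]).
#' @param min_quality,max_redundancy thresholds in percent.
#' @return `scores` subset of kept genomes, with an `unscored` column.
#' @export
final_filters <- function(scores, min_quality = 50, max_redundancy = 25) {
  keep <- !scores$scored |
    (scores$quality >= min_quality & scores$redundancy <= max_redundancy)
  out <- scores[keep, , drop = FALSE]
  out$unscored <- !out$scored
  rownames(out) <- NULL
  out
}

#' Dereplicate genomes by ANI
#'
#' Genomes linked by `ani >= ani_max` with at least
#' `min_aligned_fraction` of the shorter genome aligned are clustered by
#' single linkage; each cluster keeps the genome with the highest quality
#' score, falling back to the largest genome when no quality is
#' available. Output is invariant to input order.
#'
#' @param genomes data frame `genome_id`, `length` and optionally
#'   `quality` (may be `NA`).
#' @param ani ANI pair table (`genome_a`, `genome_b`, `ani`,
#'   `aligned_fraction`).
#' @param ani_max identity threshold defining redundancy (default 98;
#'   pairs at or above are linked, i.e. the non-redundant set satisfies
#'   ANI < 98).
#' @param min_aligned_fraction alignment-fraction gate (default 0.25).
#' @return data frame of representatives with a `cluster` column and the
#'   `n_members` each represents.
#' @export
dereplicate <- function(genomes, ani, ani_max = 98,
                        min_aligned_fraction = 0.25) {
  genomes <- genomes[order(genomes$genome_id), , drop = FALSE]
  if (!"quality" %in% names(genomes)) genomes$quality <- NA_real_
  linked <- ani[ani$ani >= ani_max &
                  ani$aligned_fraction >= min_aligned_fraction, ,
                drop = FALSE]
  g <- igraph::graph_from_data_frame(
    d = linked[, c("genome_a", "genome_b")], directed = FALSE,
    vertices = data.frame(name = genomes$genome_id))
  comp <- igraph::components(g)$membership
  genomes$cluster <- comp[genomes$genome_id]
  reps <- lapply(split(genomes, genomes$cluster), function(cl) {
    q <- cl$quality
    pick <- if (any(!is.na(q))) which(q == max(q, na.rm = TRUE) & !is.na(q))
    else seq_len(nrow(cl))
    best <- pick[order(-cl$length[pick], cl$genome_id[pick])][1]
    out <- cl[best, , drop = FALSE]
    out$n_members <- nrow(cl)
    out
  })
  res <- do.call(rbind, reps)
  res <- res[order(res$genome_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}
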