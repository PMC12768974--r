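#' Assign a high-rank taxonomic category to a contig
#'
#' A contig is assigned to the category (e.g. `Mirusviricota`, `Bacteria`,
#' `Archaea`, `Eukarya`, `plastid`, `Nucleocytoviricota`) for which at
#' least `min_fraction` of its proteins have their best hit, provided this
#' fraction is strictly greater than that of every other category;
#' otherwise the contig stays `UNASSIGNED`. Ties fail the strict-dominance
#' requirement.
#'
#' @param hits best-hit table for the contig's proteins (at most one row
#'   per protein), with a `subject_category` column.
#' @param n_proteins total number of proteins on the contig (the fraction
#'   denominator; proteins without hits count).
#' @param min_fraction minimum winning best-hit fraction (default 0.25,
#'   inclusive).
#' @return a category label or `"UNASSIGNED"`.
#' @export
assign_contig_category <- function(hits, n_proteins, min_fraction = 0.25) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (nrow(hits) == 0) return("UNASSIGNED")
  counts <- sort(table(hits$subject_category), decreasing = TRUE)
  frac <- as.numeric(counts) / n_proteins
  if (frac[1] < min_fraction) return("UNASSIGNED")
  if (length(frac) > 1 && frac[2] == frac[1]) return("UNASSIGNED")
  names(counts)[1]
}

#' Assign a clade to a mirusvirus contig
#'
#' After a contig has been assigned to the target phylum, it is assigned
#' to a clade when at least `min_fraction` of its proteins have their best
#' match in that same clade.
#'
#' @param hits best-hit table for the contig's proteins with a
#'   `subject_clade` column.
#' @param n_proteins total number of proteins on the contig.
#' @param min_fraction minimum clade best-hit fraction (default 0.50,
#'   inclusive).
#' @return a clade label or `NA` when no clade reaches the threshold.
#' @export
assign_contig_clade <- function(hits, n_proteins, min_fraction = 0.50) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  cl <- hits$subject_clade[!is.na(hits$subject_clade)]
  if (length(cl) == 0) return(NA_character_)
  counts <- sort(table(cl), decreasing = TRUE)
  if (as.numeric(counts)[1] / n_proteins < min_fraction)
    return(NA_character_)
  names(counts)[1]
}

#' Table of per-contig category and clade assignments
#'
#' Applies [assign_contig_category()] and [assign_contig_clade()] to every
#' contig with at least one predicted protein.
#'
#' @param hits community-wide best-hit table (`query_contig_id`,
#'   `subject_category`, `subject_clade`).
#' @param proteins protein table (`protein_id`, `contig_id`); provides the
#'   per-contig protein counts.
#' @param target_category category whose contigs get clade assignment.
#' @inheritParams assign_contig_category
#' @return data frame `contig_id`, `n_proteins`, `category`, `clade`.
#' @export
assign_contigs <- function(hits, proteins, target_category = "Mirusviricota",
                           min_fraction = 0.25, clade_min_fraction = 0.50) {
  counts <- table(proteins$contig_id)
  ids <- names(counts)
  hit_by_contig <- split(hits, hits$query_contig_id)
  res <- lapply(ids, function(ctg) {
    h <- hit_by_contig[[ctg]]
    if (is.null(h)) h <- hits[0, , drop = FALSE]
    n <- as.integer(counts[[ctg]])
    cat_ <- assign_contig_category(h, n, min_fraction)
    clade <- if (identical(cat_, target_category))
      assign_contig_clade(h[h$subject_category == target_category, ,
                            drop = FALSE], n, clade_min_fraction)
    else NA_character_
    data.frame(contig_id = ctg, n_proteins = n, category = cat_,
               clade = clade, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Build MAGs from bins and contig assignments
#'
#' Contigs of the same bin assigned to the same mirusvirus clade form one
#' MAG. MAGs shorter than `min_len` or longer than `max_len` are rejected
#' and recorded in the rejection ledger. Contigs shorter than
#' `min_contig` are dropped upstream.
#'
#' @param bins data frame `bin_id`, `contig_id` (a contig may belong to
#'   one bin only).
#' @param assignments output of [assign_contigs()].
#' @param contig_lengths named vector of contig lengths.
#' @param target_category category retained in MAGs.
#' @param min_len,max_len MAG total-length bounds (bp; defaults 50 kb and
#'   650 kb, exclusive rejection outside).
#' @param min_contig smallest contig considered (default 2,500 bp).
#' @return list with `mags` (data frame `mag_id`, `bin_id`, `clade`,
#'   `n_contigs`, `total_length`), `members` (`mag_id`, `contig_id`) and
#'   `rejected` (ledger with reasons).
#' @export
build_mags <- function(bins, assignments, contig_lengths,
                       target_category = "Mirusviricota",
                       min_len = 50e3, max_len = 650e3, min_contig = 2500) {
  if (anyDuplicated(bins$contig_id))
    stop("contig assigned to more than one bin: ",
         bins$contig_id[duplicated(bins$contig_id)][1])
  df <- merge(bins, assignments, by = "contig_id")
  df$length <- as.numeric(contig_lengths[df$contig_id])
  df <- df[df$length >= min_contig, , drop = FALSE]
  df <- df[df$category == target_category & !is.na(df$clade), , drop = FALSE]
  if (nrow(df) == 0)
    return(list(mags = empty_mags(), members = data.frame(
      mag_id = character(), contig_id = character()), rejected = data.frame(
        mag_id = character(), reason = character())))
  key <- paste(df$bin_id, df$clade, sep = "::")
  groups <- split(df, key)
  mags <- do.call(rbind, lapply(groups, function(g) {
    data.frame(mag_id = paste0(g$bin_id[1], "_", g$clade[1]),
               bin_id = g$bin_id[1], clade = g$clade[1],
               n_contigs = nrow(g), total_length = sum(g$length),
               stringsAsFactors = FALSE)
  }))
  members <- do.call(rbind, lapply(groups, function(g) {
    data.frame(mag_id = paste0(g$bin_id[1], "_", g$clade[1]),
               contig_id = g$contig_id, stringsAsFactors = FALSE)
  }))
  too_small <- mags$total_length < min_len
  too_big <- mags$total_length > max_len
  reason <- ifelse(too_small, "below_min_len",
                   ifelse(too_big, "above_max_len", NA_character_))
  rejected <- data.frame(mag_id = mags$mag_id[too_small | too_big],
                         reason = reason[too_small | too_big],
                         stringsAsFactors = FALSE)
  keep <- !(too_small | too_big)
  members <- members[members$mag_id %in% mags$mag_id[keep], , drop = FALSE]
  mags <- mags[keep, , drop = FALSE]
  rownames(mags) <- rownames(members) <- NULL
  list(mags = mags, members = members, rejected = rejected)
}

empty_mags <- function() {
  data.frame(mag_id = character(), bin_id = character(), clade = character(),
             n_contigs = integer(), total_length = numeric(),
             stringsAsFactors = FALSE)
}

#' Rescue highly divergent putative MAGs
#'
#' For marker-bearing bins that evade similarity-based assignment, a
#' cascade of exclusions collects contigs likely to belong to the target
#' phylum: bins larger than `bin_max_len` or with a good level of
#' reference hits (more than `bin_hit_fraction_max` of proteins) are
#' excluded; within remaining bins, contigs shorter than `contig_min_len`
#' or with more than `cellular_fraction_max` of proteins best-hitting
#' cellular categories are excluded. Surviving contigs form one putative
#' MAG per bin when their cumulative length reaches `mag_min_len`.
#'
#' @param bins data frame `bin_id`, `contig_id`.
#' @param contigs data frame `contig_id`, `length`, `has_mcp`.
#' @param hits community-wide best-hit table.
#' @param proteins protein table (`protein_id`, `contig_id`).
#' @param bin_max_len,bin_hit_fraction_max,contig_min_len,
#'   cellular_fraction_max,mag_min_len filter thresholds.
#' @param cellular_categories categories counted as cellular.
#' @return list `mags` / `members` of putative MAGs (flagged
#'   `putative = TRUE`).
#' @export
rescue_distant_mags <- function(bins, contigs, hits, proteins,
                                bin_max_len = 1e6,
                                bin_hit_fraction_max = 0.25,
                                contig_min_len = 10e3,
                                cellular_fraction_max = 0.10,
                                mag_min_len = 50e3,
                                cellular_categories = c("Bacteria",
                                                        "Archaea",
                                                        "plastid")) {
  df <- merge(bins, contigs, by = "contig_id")
  prot_counts <- table(proteins$contig_id)
  df$n_proteins <- as.integer(prot_counts[df$contig_id])
  df$n_proteins[is.na(df$n_proteins)] <- 0L
  hit_counts <- table(hits$query_contig_id)
  df$n_hit <- as.integer(hit_counts[df$contig_id])
  df$n_hit[is.na(df$n_hit)] <- 0L
  cell <- hits[hits$subject_category %in% cellular_categories, , drop = FALSE]
  cell_counts <- table(cell$query_contig_id)
  df$n_cell <- as.integer(cell_counts[df$contig_id])
  df$n_cell[is.na(df$n_cell)] <- 0L

  mags <- list(); members <- list()
  for (b in unique(df$bin_id)) {
    sub <- df[df$bin_id == b, , drop = FALSE]
    if (!any(sub$has_mcp)) next
    if (sum(sub$length) > bin_max_len) next
    np <- sum(sub$n_proteins)
    if (np > 0 && sum(sub$n_hit) / np > bin_hit_fraction_max) next
    sub <- sub[sub$length >= contig_min_len, , drop = FALSE]
    keep <- sub$n_proteins == 0 |
      sub$n_cell / pmax(sub$n_proteins, 1L) <= cellular_fraction_max
    sub <- sub[keep, , drop = FALSE]
    if (nrow(sub) == 0 || sum(sub$length) < mag_min_len) next
    mid <- paste0(b, "_putative")
    mags[[length(mags) + 1]] <- data.frame(
      mag_id = mid, bin_id = b, clade = NA_character_,
      n_contigs = nrow(sub), total_length = sum(sub$length),
      putative = TRUE, stringsAsFactors = FALSE)
    members[[length(members) + 1]] <- data.frame(
      mag_id = mid, contig_id = sub$contig_id, stringsAsFactors = FALSE)
  }
  list(mags = if (length(mags) > 0) do.call(rbind, mags) else
    cbind(empty_mags(), putative = logical(0)),
    members = if (length(members) > 0) do.call(rbind, members) else
      data.frame(mag_id = character(), contig_id = character()))
}

#' Iterative similarity-based binning
#'
#' Runs `n_iterations` passes of (alignment backend, contig assignment,
#' MAG construction); after each pass the proteins of accepted MAGs are
#' appended to the reference database so that the next pass can recruit
#' contigs matching only newly recovered genomes. A final rescue pass can
#' collect highly divergent putative MAGs.
#'
#' @param bins data frame `bin_id`, `contig_id`.
#' @param contigs data frame `contig_id`, `length`, `has_mcp`.
#' @param proteins data frame `protein_id`, `contig_id`.
#' @param ref_db reference data frame `protein_id`, `category`, `clade`
#'   (any further columns are carried along); grows across iterations.
#' @param backend function `(proteins, ref_db) -> best-hit table`; in
#'   production an adapter around an external aligner, in tests an
#'   internal scorer.
#' @param n_iterations number of recruitment passes (0 = single
#'   [build_mags()] on the initial backend output).
#' @param rescue run [rescue_distant_mags()] after the last iteration.
#' @param ... passed to [build_mags()].
#' @return list `mags`, `members`, `ref_db` (final), `rescued`.
#' @export
iterate_binning <- function(bins, contigs, proteins, ref_db, backend,
                            n_iterations = 2, rescue = TRUE, ...) {
  contig_lengths <- setNames(contigs$length, contigs$contig_id)
  run_pass <- function(db) {
    hits <- backend(proteins, db)
    asn <- assign_contigs(hits, proteins)
    list(hits = hits, built = build_mags(bins, asn, contig_lengths, ...))
  }
  pass <- run_pass(ref_db)
  iter <- 0
  while (iter < n_iterations) {
    accepted_contigs <- pass$built$members$contig_id
    new_prot <- proteins[proteins$contig_id %in% accepted_contigs, ,
                         drop = FALSE]
    if (nrow(new_prot) > 0) {
      asn <- assign_contigs(pass$hits, proteins)
      clade <- asn$clade[match(new_prot$contig_id, asn$contig_id)]
      add <- data.frame(protein_id = new_prot$protein_id,
                        category = "Mirusviricota", clade = clade,
                        stringsAsFactors = FALSE)
      add <- add[!(add$protein_id %in% ref_db$protein_id), , drop = FALSE]
      ref_db <- rbind(ref_db[, c("protein_id", "category", "clade")], add)
    }
    pass <- run_pass(ref_db)
    iter <- iter + 1
  }
  rescued <- NULL
  if (rescue) {
    assigned <- pass$built$members$contig_id
    rest_bins <- bins[!(bins$contig_id %in% assigned), , drop = FALSE]
    rescued <- rescue_distant_mags(rest_bins, contigs, pass$hits, proteins)
  }
  list(mags = pass$built$mags, members = pass$built$members,
       ref_db = ref_db, rescued = rescued)
}

#' Per-genome annotation and singleton summaries
#'
#' @param genes data frame `genome_id`, `gene_id`.
#' @param annotations data frame `gene_id`, `annotated` (logical).
#' @param clusters data frame `gene_id`, `cluster_id`; a gene may appear
#'   in at most one cluster. Genes absent from any cluster of at least two
#'   members are singletons.
#' @return data frame `genome_id`, `n_genes`, `pct_annotated`,
#'   `pct_singletons`.
#' @export
summarize_annotation <- function(genes, annotations, clusters) {
  if (anyDuplicated(clusters$gene_id))
    stop("gene assigned to more than one cluster: ",
         clusters$gene_id[duplicated(clusters$gene_id)][1])
  sizes <- table(clusters$cluster_id)
  big <- names(sizes)[sizes >= 2]
  clustered <- clusters$gene_id[clusters$cluster_id %in% big]
  out <- lapply(split(genes, genes$genome_id), function(g) {
    ids <- unique(g$gene_id)
    if (length(ids) == 0) stop("genome with no genes: ", g$genome_id[1])
    ann <- annotations$annotated[match(ids, annotations$gene_id)]
    data.frame(genome_id = g$genome_id[1], n_genes = length(ids),
               pct_annotated = 100 * mean(ann %in% TRUE),
               pct_singletons = 100 * mean(!(ids %in% clustered)),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
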