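# genomic footprint (first exon start to last exon end) of each gene in
# an exon table
model_footprints <- function(models) {
  if (nrow(models) == 0)
    return(data.frame(gene_id = character(), contig_id = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), n_exons = integer(),
                      stringsAsFactors = FALSE))
  sp <- split(models, models$gene_id)
  out <- do.call(rbind, lapply(sp, function(g) data.frame(
    gene_id = g$gene_id[1], contig_id = g$contig_id[1],
    strand = g$strand[1], start = min(g$start), end = max(g$end),
    n_exons = nrow(g), stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

overlap_len <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Arbitrate between intron-aware and intronless gene predictions
#'
#' The default merged set keeps the intron-aware model wherever one
#' exists and fills the remaining space with ORF-caller models. Two
#' correction rules then repair characteristic intron-aware failure
#' modes:
#'
#' * **Fusion (rule 1):** a multi-exon model whose exons are all longer
#'   than `min_exon_len` and each of which overlaps, by more than
#'   `overlap_min` of the exon length, a *distinct* ORF (a one-to-one
#'   exon-to-ORF assignment, found by maximum bipartite matching) is
#'   replaced by those ORFs.
#' * **Spurious short exon (rule 2):** a two-exon model whose shorter
#'   exon is less than `short_exon_fraction` of the longer one and whose
#'   genomic footprint is covered, by more than `overlap_min`, by a
#'   single ORF is replaced by that ORF.
#'
#' Every substitution is recorded in a correction ledger.
#'
#' @param intron_aware,orfs exon tables (see [models_to_features()]).
#' @param min_exon_len rule-1 minimum exon length (bp, strict).
#' @param overlap_min overlap fraction threshold (strict) for both rules.
#' @param short_exon_fraction rule-2 short/long exon ratio bound
#'   (strict).
#' @return list with `models` (merged exon table), `ledger` (data frame
#'   `gene_id`, `rule`, `replacement_ids`).
#' @export
merge_predictions <- function(intron_aware, orfs, min_exon_len = 300,
                              overlap_min = 0.95,
                              short_exon_fraction = 0.05) {
  validate_models(intron_aware)
  validate_models(orfs)
  ia_fp <- model_footprints(intron_aware)
  orf_fp <- model_footprints(orfs)

  # overlapping intron-aware models on the same strand: keep the longest
  drop <- character(0)
  for (key in unique(paste(ia_fp$contig_id, ia_fp$strand))) {
    sub <- ia_fp[paste(ia_fp$contig_id, ia_fp$strand) == key, , drop = FALSE]
    if (nrow(sub) < 2) next
    sub <- sub[order(sub$start), ]
    for (i in seq_len(nrow(sub) - 1)) {
      if (sub$gene_id[i] %in% drop) next
      j <- i + 1
      if (sub$start[j] < sub$end[i]) {
        warning("overlapping intron-aware models ", sub$gene_id[i], " and ",
                sub$gene_id[j], "; keeping the longest")
        len_i <- sub$end[i] - sub$start[i]
        len_j <- sub$end[j] - sub$start[j]
        drop <- c(drop, if (len_i >= len_j) sub$gene_id[j] else
          sub$gene_id[i])
      }
    }
  }
  ia_fp <- ia_fp[!(ia_fp$gene_id %in% drop), , drop = FALSE]
  intron_aware <- intron_aware[!(intron_aware$gene_id %in% drop), ,
                               drop = FALSE]

  ledger <- list()
  kept <- list()
  used_orfs <- character(0)

  for (gid in ia_fp$gene_id) {
    ex <- intron_aware[intron_aware$gene_id == gid, , drop = FALSE]
    ex <- ex[order(ex$start), ]
    fp <- ia_fp[ia_fp$gene_id == gid, ]
    cand <- orf_fp[orf_fp$contig_id == fp$contig_id &
                     orf_fp$strand == fp$strand &
                     orf_fp$end > fp$start & orf_fp$start < fp$end, ,
                   drop = FALSE]
    replaced <- FALSE
    if (nrow(ex) >= 2 && nrow(cand) > 0) {
      # rule 1: fused genes
      if (all(ex$end - ex$start > min_exon_len)) {
        edges <- list()
        for (i in seq_len(nrow(ex))) {
          ov <- overlap_len(ex$start[i], ex$end[i], cand$start, cand$end) /
            (ex$end[i] - ex$start[i])
          for (j in which(ov > overlap_min))
            edges[[length(edges) + 1]] <- c(i, j)
        }
        if (length(edges) > 0) {
          em <- do.call(rbind, edges)
          match_res <- bipartite_assign(nrow(ex), nrow(cand), em)
          if (all(!is.na(match_res))) {
            reps <- cand$gene_id[match_res]
            kept[[length(kept) + 1]] <-
              orfs[orfs$gene_id %in% reps, , drop = FALSE]
            used_orfs <- c(used_orfs, reps)
            ledger[[length(ledger) + 1]] <- data.frame(
              gene_id = gid, rule = "fusion",
              replacement_ids = paste(reps, collapse = ","),
              stringsAsFactors = FALSE)
            replaced <- TRUE
          }
        }
      }
      # rule 2: spurious short exon (two-exon models only)
      if (!replaced && nrow(ex) == 2) {
        lens <- ex$end - ex$start
        short <- min(lens); long <- max(lens)
        if (short < short_exon_fraction * long) {
          fp_len <- fp$end - fp$start
          cover <- overlap_len(fp$start, fp$end, cand$start, cand$end) / fp_len
          j <- which.max(cover)
          if (length(j) == 1 && cover[j] > overlap_min) {
            rep_id <- cand$gene_id[j]
            kept[[length(kept) + 1]] <-
              orfs[orfs$gene_id == rep_id, , drop = FALSE]
            used_orfs <- c(used_orfs, rep_id)
            ledger[[length(ledger) + 1]] <- data.frame(
              gene_id = gid, rule = "spurious_exon",
              replacement_ids = rep_id, stringsAsFactors = FALSE)
            replaced <- TRUE
          }
        }
      }
    }
    if (!replaced) kept[[length(kept) + 1]] <- ex
  }

  merged <- do.call(rbind, kept)
  # ORF models elsewhere: not overlapping any retained model on the same
  # contig and strand, and not already used as a replacement
  mfp <- model_footprints(merged)
  free <- vapply(seq_len(nrow(orf_fp)), function(j) {
    o <- orf_fp[j, ]
    if (o$gene_id %in% used_orfs) return(FALSE)
    hit <- mfp$contig_id == o$contig_id & mfp$strand == o$strand &
      mfp$end > o$start & mfp$start < o$end
    !any(hit)
  }, logical(1))
  merged <- rbind(merged, orfs[orfs$gene_id %in% orf_fp$gene_id[free], ,
                               drop = FALSE])
  merged <- merged[order(merged$contig_id, merged$start, merged$gene_id), ]
  rownames(merged) <- NULL
  ledger_df <- if (length(ledger) > 0) do.call(rbind, ledger) else
    data.frame(gene_id = character(), rule = character(),
               replacement_ids = character(), stringsAsFactors = FALSE)
  list(models = merged, ledger = ledger_df)
}

# maximum bipartite matching of exons to ORFs; returns, per exon, the
# matched ORF index or NA. A perfect matching must also use distinct ORFs.
bipartite_assign <- function(n_left, n_right, edges) {
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n_left), rep(TRUE, n_right)),
    edges = as.vector(t(cbind(edges[, 1], n_left + edges[, 2]))))
  m <- igraph::max_bipartite_match(g)
  idx <- m$matching[seq_len(n_left)]
  ifelse(is.na(idx), NA_integer_, as.integer(idx) - n_left)
}

#' Extract introns from gene models
#'
#' Emits one record per inter-exon gap with donor and acceptor
#' dinucleotides read 5'->3' on the coding strand (minus-strand genes are
#' reverse-complemented), the oriented intron sequence, 10 bp exonic
#' flanks, and a splice class: `major` for GT..AG, `minor` for AT..AC,
#' `noncanonical` otherwise.
#'
#' @param models exon table.
#' @param sequences named character vector of contig sequences.
#' @param flank flank length (bp).
#' @return intron record data frame.
#' @export
extract_introns <- function(models, sequences, flank = 10) {
  validate_models(models)
  sp <- split(models, models$gene_id)
  rows <- list()
  for (g in sp) {
    if (nrow(g) < 2) next
    g <- g[order(g$start), ]
    ctg <- g$contig_id[1]
    seq <- sequences[[ctg]]
    if (is.null(seq) || is.na(seq)) stop("missing sequence for ", ctg)
    clen <- nchar(seq)
    strand <- g$strand[1]
    for (i in seq_len(nrow(g) - 1)) {
      s <- g$end[i]; e <- g$start[i + 1]
      if (e - s < 4)
        stop("gene ", g$gene_id[1], ": intron shorter than 4 bp")
      iseq <- substr(seq, s + 1, e)
      up <- substr(seq, max(1, s - flank + 1), s)
      dn <- substr(seq, e + 1, min(clen, e + flank))
      if (strand == "-") {
        iseq <- revcomp(iseq)
        tmp <- revcomp(up); up <- revcomp(dn); dn <- tmp
      }
      donor <- substr(iseq, 1, 2)
      acceptor <- substr(iseq, nchar(iseq) - 1, nchar(iseq))
      cls <- if (donor == "GT" && acceptor == "AG") "major"
      else if (donor == "AT" && acceptor == "AC") "minor"
      else "noncanonical"
      # transcript-order index of this gap
      idx <- if (strand == "+") i else nrow(g) - i
      rows[[length(rows) + 1]] <- data.frame(
        intron_id = paste0(g$gene_id[1], ".i", idx),
        gene_id = g$gene_id[1], contig_id = ctg, strand = strand,
        start = s, end = e, length = e - s, donor = donor,
        acceptor = acceptor, splice_class = cls, seq = iseq,
        upstream_flank = up, downstream_flank = dn,
        flank_truncated = nchar(up) < flank | nchar(dn) < flank,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(intron_id = character(), gene_id = character(),
               contig_id = character(), strand = character(),
               start = numeric(), end = numeric(), length = numeric(),
               donor = character(), acceptor = character(),
               splice_class = character(), seq = character(),
               upstream_flank = character(), downstream_flank = character(),
               flank_truncated = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter junction evidence by read support
#'
#' @param junctions junction evidence table with a `read_count` column.
#' @param min_reads minimum supporting reads (default 10, inclusive).
#' @return supported subset of `junctions`.
#' @export
filter_junctions <- function(junctions, min_reads = 10) {
  out <- junctions[junctions$read_count >= min_reads, , drop = FALSE]
  rownames(out) <- NULL
  out
}
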