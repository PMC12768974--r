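#' Intron density of a gene set
#'
#' Density is the number of introns per kb of gene sequence, where gene
#' length is the genomic footprint of the exon chain (first exon start to
#' last exon end, introns included).
#'
#' @param models exon table.
#' @param introns intron table with a `gene_id` column.
#' @param scope optional character vector of gene ids restricting the
#'   computation (e.g. the morphogenesis module); default all genes.
#' @param footprint if `FALSE`, use summed exon length instead of the
#'   genomic footprint as denominator.
#' @return introns per kb (numeric scalar).
#' @export
intron_density <- function(models, introns, scope = NULL, footprint = TRUE) {
  fp <- model_footprints(models)
  if (!is.null(scope)) {
    fp <- fp[fp$gene_id %in% scope, , drop = FALSE]
    introns <- introns[introns$gene_id %in% scope, , drop = FALSE]
  }
  total_kb <- if (footprint) sum(fp$end - fp$start) / 1000 else {
    sub <- models[models$gene_id %in% fp$gene_id, , drop = FALSE]
    sum(sub$end - sub$start) / 1000
  }
  if (total_kb <= 0) stop("zero total gene length in scope")
  nrow(introns) / total_kb
}

#' Intron enrichment of a gene class
#'
#' Compares intron density inside a labelled gene class (typically the
#' virion morphogenesis module) against the rest of the genes.
#'
#' @param models exon table.
#' @param introns intron table.
#' @param label_genes gene ids in the labelled class.
#' @param footprint denominator choice, as in [intron_density()]:
#'   genomic footprint (default) or summed exon length.
#' @return list with `density_in`, `density_out`, `ratio`,
#'   `intron_share_pct` (percent of introns falling in the class) and
#'   `infinite` flag (`density_out == 0`).
#' @export
enrichment_ratio <- function(models, introns, label_genes,
                             footprint = TRUE) {
  all_genes <- unique(models$gene_id)
  inside <- intersect(all_genes, label_genes)
  outside <- setdiff(all_genes, label_genes)
  if (length(inside) == 0 || length(outside) == 0)
    stop("both gene classes must be non-empty")
  d_in <- intron_density(models, introns, scope = inside,
                         footprint = footprint)
  d_out <- intron_density(models, introns, scope = outside,
                          footprint = footprint)
  n_in <- sum(introns$gene_id %in% inside)
  list(density_in = d_in, density_out = d_out,
       ratio = if (d_out == 0) Inf else d_in / d_out,
       intron_share_pct = 100 * n_in / max(1, nrow(introns)),
       infinite = d_out == 0)
}

# oriented branch-point search region of one intron sequence: the window
# [window[1], window[2]] (negative offsets) relative to the intron 3' end
branch_window_region <- function(seq, window) {
  len <- nchar(seq)
  lo <- len + window[1] + 1  # 1-based start of the window
  hi <- len + window[2]
  if (lo < 3 || hi < lo) return(NA_character_)  # would run into the donor
  substr(seq, lo, hi)
}

#' Fraction of introns with a branch-point motif in the acceptor window
#'
#' Searches the window (default `[-40, -10]` relative to the intron 3'
#' end) of each oriented intron sequence for at least one match of an
#' IUPAC motif. Introns too short to hold the window are skipped and
#' flagged.
#'
#' @param introns intron table with a `seq` column (oriented sequences).
#' @param motif IUPAC motif string.
#' @param window integer window `c(from, to)` of negative offsets from
#'   the acceptor end.
#' @return list with `fraction` (among scanned introns), `flags` (per
#'   intron: `match`, `no_match` or `skipped`).
#' @export
motif_fraction <- function(introns, motif, window = c(-40, -10)) {
  rx <- iupac_to_regex(motif)
  regions <- vapply(introns$seq, branch_window_region, character(1),
                    window = window, USE.NAMES = FALSE)
  skipped <- is.na(regions)
  hit <- !skipped & grepl(rx, regions)
  flags <- ifelse(skipped, "skipped", ifelse(hit, "match", "no_match"))
  n_scanned <- sum(!skipped)
  list(fraction = if (n_scanned == 0) NA_real_ else sum(hit) / n_scanned,
       flags = flags)
}

# Altschul-Erikson dinucleotide-preserving shuffle of one sequence
dinuc_shuffle <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  letters_ <- unique(ch)
  last <- ch[n]
  succ <- lapply(setNames(letters_, letters_), function(v)
    ch[which(ch[-n] == v) + 1])
  for (attempt in 1:100) {
    shuffled <- lapply(succ, sample)
    # chosen last edges must form a walk-terminating tree into `last`
    last_edge <- vapply(letters_, function(v) {
      e <- shuffled[[v]]
      if (length(e) == 0) NA_character_ else e[length(e)]
    }, character(1))
    ok <- TRUE
    for (v in setdiff(letters_, last)) {
      cur <- v; seen <- character(0)
      repeat {
        nxt <- last_edge[[cur]]
        if (is.na(nxt)) { ok <- FALSE; break }
        if (nxt == last) break
        if (nxt %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- nxt
      }
      if (!ok) break
    }
    if (!ok) next
    # walk the shuffled adjacency lists
    idx <- setNames(rep(1L, length(letters_)), letters_)
    out <- character(n)
    out[1] <- ch[1]
    cur <- ch[1]
    good <- TRUE
    for (i in 2:n) {
      lst <- shuffled[[cur]]
      k <- idx[[cur]]
      if (k > length(lst)) { good <- FALSE; break }
      idx[[cur]] <- k + 1L
      cur <- lst[k]
      out[i] <- cur
    }
    if (good) return(paste(out, collapse = ""))
  }
  paste(sample(ch), collapse = "")  # fallback: plain shuffle
}

#' Discover over-represented branch-point k-mers
#'
#' Ranks k-mers (k in `k_range`) by over-representation of
#' intron-containing windows versus a dinucleotide-preserving shuffled
#' background, using a binomial upper-tail test against the pooled
#' shuffle frequency with Benjamini-Hochberg correction across tested
#' k-mers.
#'
#' @param introns intron table with oriented `seq` column; at least 50
#'   introns are required.
#' @param k_range k-mer sizes (default 5:7).
#' @param window acceptor-relative search window.
#' @param n_shuffles shuffled backgrounds per window (default 100).
#' @param fdr false-discovery-rate cut-off.
#' @return data frame of significant motifs ranked by enrichment:
#'   `motif`, `fraction`, `background`, `enrichment`, `p`, `padj`.
#' @export
discover_branch_motif <- function(introns, k_range = 5:7,
                                  window = c(-40, -10), n_shuffles = 100,
                                  fdr = 0.05) {
  regions <- vapply(introns$seq, branch_window_region, character(1),
                    window = window, USE.NAMES = FALSE)
  regions <- regions[!is.na(regions)]
  if (length(regions) < 50)
    stop("at least 50 introns with a full search window are required")
  n <- length(regions)
  bg <- unlist(lapply(regions, function(r)
    replicate(n_shuffles, dinuc_shuffle(r))))
  kmer_windows <- function(strs, k) {
    # which k-mers occur in each string (presence, not counts)
    lapply(strs, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      unique(substring(s, 1:(L - k + 1), k:L))
    })
  }
  rows <- list()
  for (k in k_range) {
    obs <- kmer_windows(regions, k)
    obs_tab <- table(unlist(obs))
    bg_tab <- table(unlist(kmer_windows(bg, k)))
    kmers <- names(obs_tab)
    p_bg <- (as.numeric(bg_tab[kmers]) + 1) / (length(bg) + 2)
    p_bg[is.na(p_bg)] <- 1 / (length(bg) + 2)
    x <- as.numeric(obs_tab)
    pval <- pbinom(x - 1, n, pmin(p_bg, 1), lower.tail = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      motif = kmers, fraction = x / n, background = p_bg,
      p = pval, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows)
  res$padj <- p.adjust(res$p, method = "BH")
  res <- res[res$padj < fdr, , drop = FALSE]
  res$enrichment <- res$fraction / res$background
  res <- res[order(res$p, -res$enrichment, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("motif", "fraction", "background", "enrichment", "p", "padj")]
}

#' Local pairwise alignment with a Karlin-Altschul e-value
#'
#' Affine-gap Smith-Waterman alignment (match +2, mismatch -3, gap open
#' 5, gap extend 2 by default) with an ungapped Karlin-Altschul e-value
#' `E = K * m * n * exp(-lambda * S)` (nucleotide defaults K = 0.41,
#' lambda = 0.625).
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters. A gap of
#'   length L costs `gap_open + L * gap_extend`.
#' @param K,lambda Karlin-Altschul parameters.
#' @return list with `score`, `evalue`, and the 1-based inclusive
#'   alignment extents `a_start`, `a_end`, `b_start`, `b_end`.
#' @export
align_local <- function(a, b, match = 2, mismatch = -3, gap_open = 5,
                        gap_extend = 2, K = 0.41, lambda = 0.625) {
  res <- sw_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  res$evalue <- K * nchar(a) * nchar(b) * exp(-lambda * res$score)
  res
}

#' Detect introner candidates
#'
#' An introner candidate is a group of at least two introns from the
#' same genome with high mutual sequence similarity. Pairs are compared
#' with flanked sequences (`upstream_flank + seq + downstream_flank`);
#' a pair passes when its local alignment reaches `evalue_max`, and is
#' rejected when the alignment extends into the exon flanks on both
#' sequences (more than `flank_tolerance` bp of flank consumed), which
#' identifies similar introns of paralogous genes rather than mobile
#' introns. Passing pairs are grouped per genome by single linkage.
#'
#' @param introns intron table with `seq`, `upstream_flank`,
#'   `downstream_flank` and a `genome_id` (or `contig_id`-derived)
#'   column.
#' @param evalue_max pair-acceptance e-value (default 1e-5).
#' @param flank flank length attached to the sequences (default 10).
#' @param flank_tolerance flank bases an alignment may consume before it
#'   counts as extending into the exons (default 2).
#' @param pairs optional pre-computed pair table (`intron_a`,
#'   `intron_b`, `evalue`, `a_flank_hit`, `b_flank_hit`) imported from an
#'   external aligner; bypasses the internal aligner.
#' @return data frame of group members: `genome_id`, `group`,
#'   `intron_id`, `representative`.
#' @export
detect_introners <- function(introns, evalue_max = 1e-5, flank = 10,
                             flank_tolerance = 2, pairs = NULL) {
  if (nrow(introns) == 0)
    return(data.frame(genome_id = character(), group = integer(),
                      intron_id = character(), representative = logical(),
                      stringsAsFactors = FALSE))
  if (!"genome_id" %in% names(introns))
    stop("introns must carry a genome_id column")
  if (any(!nzchar(introns$upstream_flank)) ||
      any(!nzchar(introns$downstream_flank)))
    stop("introns are missing flank sequences")
  introns <- introns[order(introns$intron_id), , drop = FALSE]
  edges <- list()
  if (is.null(pairs)) {
    for (gid in sort(unique(introns$genome_id))) {
      sub <- introns[introns$genome_id == gid, , drop = FALSE]
      if (nrow(sub) < 2) next
      flanked <- paste0(sub$upstream_flank, sub$seq, sub$downstream_flank)
      up_len <- nchar(sub$upstream_flank)
      ilen <- nchar(sub$seq)
      for (i in seq_len(nrow(sub) - 1)) {
        for (j in (i + 1):nrow(sub)) {
          al <- align_local(flanked[i], flanked[j])
          if (al$evalue > evalue_max || al$score <= 0) next
          in_flank <- function(k, st, en) {
            lo <- up_len[k]; hi <- up_len[k] + ilen[k]
            max(0, lo - (st - 1)) + max(0, en - hi)
          }
          a_ext <- in_flank(i, al$a_start, al$a_end) > flank_tolerance
          b_ext <- in_flank(j, al$b_start, al$b_end) > flank_tolerance
          if (a_ext && b_ext) next  # paralogous-flank exclusion
          edges[[length(edges) + 1]] <- data.frame(
            genome_id = gid, intron_a = sub$intron_id[i],
            intron_b = sub$intron_id[j], stringsAsFactors = FALSE)
        }
      }
    }
  } else {
    ok <- pairs$evalue <= evalue_max &
      !(pairs$a_flank_hit & pairs$b_flank_hit)
    p <- pairs[ok, , drop = FALSE]
    gm <- introns$genome_id[match(p$intron_a, introns$intron_id)]
    gm2 <- introns$genome_id[match(p$intron_b, introns$intron_id)]
    p <- p[!is.na(gm) & !is.na(gm2) & gm == gm2, , drop = FALSE]
    if (nrow(p) > 0)
      edges[[1]] <- data.frame(
        genome_id = introns$genome_id[match(p$intron_a, introns$intron_id)],
        intron_a = p$intron_a, intron_b = p$intron_b,
        stringsAsFactors = FALSE)
  }
  if (length(edges) == 0)
    return(data.frame(genome_id = character(), group = integer(),
                      intron_id = character(), representative = logical(),
                      stringsAsFactors = FALSE))
  ed <- do.call(rbind, edges)
  verts <- sort(unique(c(ed$intron_a, ed$intron_b)))
  g <- igraph::graph_from_data_frame(ed[, c("intron_a", "intron_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = verts))
  comp <- igraph::components(g)$membership
  out <- data.frame(intron_id = names(comp), group = as.integer(comp),
                    stringsAsFactors = FALSE)
  out$genome_id <- introns$genome_id[match(out$intron_id,
                                           introns$intron_id)]
  out <- out[order(out$group, out$intron_id), , drop = FALSE]
  out$representative <- !duplicated(out$group)
  rownames(out) <- NULL
  out[, c("genome_id", "group", "intron_id", "representative")]
}

#' Find open reading frames nested in long introns
#'
#' Scans both strands of every intron longer than `min_intron` bp for
#' open reading frames (start codon to stop codon, standard genetic
#' code) longer than `min_aa` amino acids (stop excluded).
#'
#' @param introns intron table with oriented `seq` column.
#' @param min_intron introns at or below this length are never scanned
#'   (default 300 bp, strict: only introns `> min_intron` are scanned).
#' @param min_aa minimum ORF length in amino acids (strict).
#' @param start_codons allowed start codons (default `"ATG"`).
#' @return data frame `intron_id`, `orf_start`, `orf_end` (0-based
#'   half-open within the oriented intron), `strand` (relative to the
#'   intron), `aa_length`.
#' @export
find_nested_orfs <- function(introns, min_intron = 300, min_aa = 100,
                             start_codons = "ATG") {
  scan <- introns[introns$length > min_intron, , drop = FALSE]
  rows <- list()
  stops <- c("TAA", "TAG", "TGA")
  for (r in seq_len(nrow(scan))) {
    iseq <- scan$seq[r]
    L <- nchar(iseq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") iseq else revcomp(iseq)
      for (frame in 0:2) {
        n_cod <- (L - frame) %/% 3
        if (n_cod < min_aa + 2) next
        cods <- substring(s, frame + 1 + 3 * (0:(n_cod - 1)),
                          frame + 3 * (1:n_cod))
        is_stop <- cods %in% stops
        is_start <- cods %in% start_codons
        seg_start <- 1L
        for (pos in c(which(is_stop), n_cod + 1L)) {
          if (pos > seg_start) {
            starts <- which(is_start[seg_start:(pos - 1)]) + seg_start - 1L
            if (length(starts) > 0 && pos <= n_cod) {
              a <- starts[1]
              aa_len <- pos - a - 1L  # codons between start and stop
              if (aa_len > min_aa) {
                c_start <- frame + 3L * (a - 1L)        # 0-based on s
                c_end <- frame + 3L * pos               # past the stop
                if (strand == "-") {
                  tmp <- L - c_end
                  c_end <- L - c_start
                  c_start <- tmp
                }
                rows[[length(rows) + 1]] <- data.frame(
                  intron_id = scan$intron_id[r], orf_start = c_start,
                  orf_end = c_end, strand = strand, aa_length = aa_len,
                  stringsAsFactors = FALSE)
              }
            }
          }
          seg_start <- pos + 1L
        }
      }
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(intron_id = character(), orf_start = integer(),
               orf_end = integer(), strand = character(),
               aa_length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Chi-squared test of intron target specificity
#'
#' Pearson chi-squared test (no continuity correction) on a contingency
#' table of target gene classes versus nested-endonuclease families.
#'
#' @param table integer matrix (at least 2 x 2) of non-negative counts.
#' @return list `chi2`, `df`, `p`.
#' @export
target_specificity_test <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero row or column margin")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value))
}

#' Detect trans-splice events
#'
#' A supported junction whose donor falls at or inside one gene model and
#' whose acceptor falls at or inside a *different* model, separated by at
#' least `min_separation` bp (or sitting on opposite strands), with
#' canonical GT/AG dinucleotides at the genomic splice sites (after
#' strand orientation), is reported as a trans-splice event.
#'
#' @param junctions junction evidence table.
#' @param models exon table of gene models.
#' @param sequences named character vector of contig sequences.
#' @param min_reads evidence threshold (default 10).
#' @param min_separation minimum genomic separation for same-strand
#'   events (default 1 kb).
#' @return data frame of events: fragment gene ids, junction positions,
#'   separation, `same_strand`, read support.
#' @export
detect_trans_splice <- function(junctions, models, sequences,
                                min_reads = 10, min_separation = 1000) {
  j <- filter_junctions(junctions, min_reads)
  fp <- model_footprints(models)
  rows <- list()
  locate <- function(ctg, pos, strand) {
    hit <- fp$contig_id == ctg & fp$strand == strand &
      pos >= fp$start & pos <= fp$end
    if (!any(hit)) return(NA_character_)
    fp$gene_id[which(hit)[1]]
  }
  for (i in seq_len(nrow(j))) {
    row <- j[i, ]
    seq <- sequences[[row$contig_id]]
    if (is.null(seq)) next
    gA <- locate(row$contig_id, row$donor_pos, row$donor_strand)
    gB <- locate(row$contig_id, row$acceptor_pos, row$acceptor_strand)
    if (is.na(gA) || is.na(gB) || gA == gB) next
    same_strand <- row$donor_strand == row$acceptor_strand
    sep <- abs(row$acceptor_pos - row$donor_pos)
    if (same_strand && sep < min_separation) next
    donor_dinuc <- if (row$donor_strand == "+")
      substr(seq, row$donor_pos + 1, row$donor_pos + 2)
    else revcomp(substr(seq, row$donor_pos - 1, row$donor_pos))
    acc_dinuc <- if (row$acceptor_strand == "+")
      substr(seq, row$acceptor_pos - 1, row$acceptor_pos)
    else revcomp(substr(seq, row$acceptor_pos + 1, row$acceptor_pos + 2))
    if (donor_dinuc != "GT" || acc_dinuc != "AG") next
    rows[[length(rows) + 1]] <- data.frame(
      contig_id = row$contig_id, fragment_a = gA, fragment_b = gB,
      donor_pos = row$donor_pos, acceptor_pos = row$acceptor_pos,
      separation = sep, same_strand = same_strand,
      read_count = row$read_count, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(contig_id = character(), fragment_a = character(),
               fragment_b = character(), donor_pos = numeric(),
               acceptor_pos = numeric(), separation = numeric(),
               same_strand = logical(), read_count = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
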