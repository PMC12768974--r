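#' Coordinate conventions
#'
#' All internal coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive), on the forward strand of the contig. GFF3 input and output
#' converts to and from the 1-based inclusive convention at the boundary.
#'
#' @param start,end numeric vectors of GFF3 (1-based inclusive) or internal
#'   (0-based half-open) coordinates.
#' @return a data frame with converted `start` and `end` columns.
#' @examples
#' gff_to_internal(101, 200)  # -> start 100, end 200
#' @export
gff_to_internal <- function(start, end) {
  data.frame(start = start - 1, end = end)
}

#' @rdname gff_to_internal
#' @export
internal_to_gff <- function(start, end) {
  data.frame(start = start + 1, end = end)
}

#' Validate genomic intervals
#'
#' Checks the 0-based half-open interval invariants: `0 <= start < end`,
#' and `end <= contig length` when contig lengths are supplied.
#'
#' @param df data frame with `contig_id`, `start`, `end` (and optionally
#'   `strand`) columns.
#' @param contig_lengths optional named vector of contig lengths.
#' @return `df`, invisibly; stops on violation.
#' @export
validate_intervals <- function(df, contig_lengths = NULL) {
  check_columns(df, c("contig_id", "start", "end"), "interval table")
  bad <- which(df$start < 0 | df$end <= df$start)
  if (length(bad) > 0)
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": require 0 <= start < end")
  if ("strand" %in% names(df)) {
    badstr <- which(!df$strand %in% c("+", "-"))
    if (length(badstr) > 0)
      stop("invalid strand at row(s) ", paste(head(badstr, 5), collapse = ", "))
  }
  if (!is.null(contig_lengths)) {
    len <- contig_lengths[df$contig_id]
    bad <- which(!is.na(len) & df$end > len)
    if (length(bad) > 0)
      stop("interval(s) beyond contig end at row(s) ",
           paste(head(bad, 5), collapse = ", "))
  }
  invisible(df)
}

#' Read and write FASTA
#'
#' Sequences are returned as a named character vector, upper-cased.
#' Lowercase (soft-masked) positions can be recorded as a per-sequence mask
#' but are not used by any downstream rule.
#'
#' @param path file path.
#' @param mask if `TRUE`, attach a `mask` attribute: a list (one element per
#'   sequence) of integer vectors of soft-masked (lowercase) positions.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path, mask = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- as.character(ss)
  out <- toupper(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (any(grepl("[^ACGTN]", out)))
    stop("FASTA contains characters outside the ACGTN alphabet: ", path)
  if (mask) {
    attr(out, "mask") <- lapply(seqs, function(s)
      which(strsplit(s, "", fixed = TRUE)[[1]] %in% c("a", "c", "g", "t", "n")))
  }
  out
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a GFF3 file into a feature table
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' and `Parent` links are resolved into a `parent_id` column.
#'
#' @param path GFF3 file path.
#' @return data frame with columns `feature_id`, `feature_type`,
#'   `contig_id`, `start`, `end`, `strand`, `parent_id`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(lines))
  for (i in body) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != 9)
      stop("malformed GFF3 line ", i, " in ", path, ": expected 9 fields, got ",
           length(fields))
    s <- suppressWarnings(as.numeric(fields[4]))
    e <- suppressWarnings(as.numeric(fields[5]))
    if (is.na(s) || is.na(e))
      stop("malformed GFF3 line ", i, " in ", path, ": non-numeric coordinates")
    if (e < s)
      stop("invalid GFF3 line ", i, " in ", path, ": end < start")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  id <- as.character(gr$ID)
  if (is.null(gr$ID)) id <- rep(NA_character_, length(gr))
  id[is.na(id)] <- paste0("feature_", which(is.na(id)))
  parent <- rep(NA_character_, length(gr))
  if (!is.null(gr$Parent)) {
    has_par <- lengths(gr$Parent) > 0
    parent[has_par] <- vapply(as.list(gr$Parent[has_par]), `[`, character(1), 1)
  }
  data.frame(
    feature_id = id,
    feature_type = as.character(gr$type),
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    parent_id = parent,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_gff3
#' @param features feature table as returned by [read_gff3()].
#' @export
write_gff3 <- function(features, path) {
  check_columns(features, c("feature_id", "feature_type", "contig_id",
                            "start", "end", "strand"), "feature table")
  validate_intervals(features)
  strand <- features$strand
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig_id,
    ranges = IRanges::IRanges(start = features$start + 1, end = features$end),
    strand = strand
  )
  gr$type <- features$feature_type
  gr$ID <- features$feature_id
  parent <- features$parent_id
  if (is.null(parent)) parent <- rep(NA_character_, nrow(features))
  gr$Parent <- IRanges::CharacterList(lapply(parent, function(p)
    if (is.na(p)) character() else p))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Convert between gene-model exon tables and GFF3 feature tables
#'
#' A gene model set is a data frame of exons with columns `gene_id`,
#' `contig_id`, `strand`, `start`, `end` and optionally `source`
#' (`"intron_aware"` or `"orf"`). Exons of a gene must share contig and
#' strand and be pairwise disjoint.
#'
#' @param models exon table.
#' @return feature table (gene rows plus exon rows with `parent_id`).
#' @export
models_to_features <- function(models) {
  check_columns(models, c("gene_id", "contig_id", "strand", "start", "end"),
                "gene model table")
  models <- models[order(models$gene_id, models$start), , drop = FALSE]
  sp <- split(models, models$gene_id)
  genes <- do.call(rbind, lapply(sp, function(g) {
    data.frame(feature_id = g$gene_id[1], feature_type = "gene",
               contig_id = g$contig_id[1], start = min(g$start),
               end = max(g$end), strand = g$strand[1],
               parent_id = NA_character_, stringsAsFactors = FALSE)
  }))
  exons <- do.call(rbind, lapply(sp, function(g) {
    data.frame(feature_id = paste0(g$gene_id, ".exon", seq_len(nrow(g))),
               feature_type = "exon", contig_id = g$contig_id,
               start = g$start, end = g$end, strand = g$strand,
               parent_id = g$gene_id, stringsAsFactors = FALSE)
  }))
  out <- rbind(genes, exons)
  rownames(out) <- NULL
  out
}

#' @rdname models_to_features
#' @param features feature table with gene and exon rows.
#' @param source optional source tag to attach to the resulting models.
#' @export
features_to_models <- function(features, source = NA_character_) {
  ex <- features[features$feature_type %in% c("exon", "CDS"), , drop = FALSE]
  if (nrow(ex) == 0) {
    # single-exon gene sets may be encoded as bare gene features
    ex <- features[features$feature_type == "gene", , drop = FALSE]
    ex$parent_id <- ex$feature_id
  }
  out <- data.frame(gene_id = ex$parent_id, contig_id = ex$contig_id,
                    strand = ex$strand, start = ex$start, end = ex$end,
                    source = source, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  validate_models(out)
  out
}

#' Validate a gene-model exon table
#'
#' Checks that exons of a gene share contig and strand, are pairwise
#' disjoint, and that inter-exon gaps (introns) are at least `min_intron`
#' bp long.
#'
#' @param models exon table.
#' @param min_intron minimum inter-exon gap (default 4 bp: donor plus
#'   acceptor dinucleotides).
#' @return `models`, invisibly.
#' @export
validate_models <- function(models, min_intron = 4) {
  validate_intervals(models)
  for (g in split(models, models$gene_id)) {
    if (length(unique(g$contig_id)) > 1 || length(unique(g$strand)) > 1)
      stop("gene ", g$gene_id[1], ": exons disagree on contig or strand")
    if (nrow(g) > 1) {
      g <- g[order(g$start), ]
      gaps <- g$start[-1] - g$end[-nrow(g)]
      if (any(gaps < min_intron))
        stop("gene ", g$gene_id[1], ": inter-exon gap shorter than ",
             min_intron, " bp (overlapping or degenerate exons)")
    }
  }
  invisible(models)
}

#' Read a tabular best-hit file (12-column alignment dialect)
#'
#' Expects tab-separated rows of `query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore` where
#' subject identifiers carry `category|clade|protein` labels. Only the best
#' hit per query is retained: highest bitscore, ties broken by higher
#' percent identity, then lexicographically smallest subject id.
#'
#' Query identifiers are expected to follow the `<contig_id>.p<n>`
#' convention from which the query contig is recovered.
#'
#' @param path file path.
#' @return data frame of best hits, one row per query, with parsed
#'   `subject_category` and `subject_clade` columns.
#' @export
read_hits <- function(path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  raw <- tryCatch(
    read.delim(path, header = FALSE, col.names = cols,
               stringsAsFactors = FALSE),
    error = function(e) {
      if (grepl("no lines available", conditionMessage(e)))
        return(NULL)
      stop(e)
    })
  if (is.null(raw) || nrow(raw) == 0) return(empty_hits())
  parts <- strsplit(raw$subject, "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0)
    stop("unparseable subject label at row ", bad[1], ": '",
         raw$subject[bad[1]], "' (expected category|clade|protein)")
  raw$subject_category <- vapply(parts, `[`, character(1), 1)
  raw$subject_clade <- vapply(parts, `[`, character(1), 2)
  raw$subject_clade[raw$subject_clade == ""] <- NA_character_
  raw$subject_protein <- vapply(parts, `[`, character(1), 3)
  best_hits(raw)
}

#' Select best hits per query
#'
#' @param hits hit table with at least `query`, `subject`, `pident`,
#'   `bitscore` columns.
#' @return one row per query after applying the tie rule (bitscore, then
#'   percent identity, then lexicographic subject id).
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query, -hits$bitscore, -hits$pident, hits$subject)
  hits <- hits[ord, , drop = FALSE]
  out <- hits[!duplicated(hits$query), , drop = FALSE]
  out$query_protein_id <- out$query
  out$query_contig_id <- sub("\\.p[0-9]+$", "", out$query)
  rownames(out) <- NULL
  out
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(), pident = numeric(),
             length = numeric(), mismatch = numeric(), gapopen = numeric(),
             qstart = numeric(), qend = numeric(), sstart = numeric(),
             send = numeric(), evalue = numeric(), bitscore = numeric(),
             subject_category = character(), subject_clade = character(),
             subject_protein = character(), query_protein_id = character(),
             query_contig_id = character(), stringsAsFactors = FALSE)
}

#' @rdname read_hits
#' @param hits hit table (pre-parse columns, i.e. `query` through
#'   `bitscore`).
#' @export
write_hits <- function(hits, path) {
  cols <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  check_columns(hits, cols, "hit table")
  write.table(hits[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read and write the pipeline's TSV tables
#'
#' Thin, schema-checked wrappers: junction evidence tables
#' (`contig_id`, `donor_pos`, `acceptor_pos`, `donor_strand`,
#' `acceptor_strand`, `read_count`), ANI tables (`genome_a`, `genome_b`,
#' `ani`, `aligned_fraction`) and protein-cluster membership tables
#' (`genome_id`, `contig_id`, `gene_id`, `cluster_id`).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_junctions <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("contig_id", "donor_pos", "acceptor_pos",
                      "donor_strand", "acceptor_strand", "read_count"),
                "junction table")
  if (any(df$read_count < 0)) stop("negative read counts in junction table")
  df
}

#' @rdname read_junctions
#' @param df table to write.
#' @export
write_junctions <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_junctions
#' @export
read_ani <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("genome_a", "genome_b", "ani", "aligned_fraction"),
                "ANI table")
  if (any(df$ani < 0 | df$ani > 100)) stop("ANI values outside [0, 100]")
  df
}

#' @rdname read_junctions
#' @export
write_ani <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_junctions
#' @export
read_clusters <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("genome_id", "contig_id", "gene_id", "cluster_id"),
                "cluster membership table")
  df
}

#' @rdname read_junctions
#' @export
write_clusters <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write newick trees with dual node supports
#'
#' Trees are `ape::phylo` objects. Internal node labels of the form
#' `"aLRT/UFBoot"` (e.g. `"85/96"`) are parsed by [parse_node_support()].
#'
#' @param path newick file path.
#' @return an `ape::phylo` object.
#' @export
read_tree <- function(path) {
  ape::read.tree(path)
}

#' @rdname read_tree
#' @param tree `ape::phylo` object.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, path)
  invisible(path)
}

#' @rdname read_tree
#' @return for `parse_node_support`, a data frame with one row per internal
#'   node (`node`, `alrt`, `ufboot`); unlabelled nodes get `NA`.
#' @export
parse_node_support <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- tree$Nnode
  labels <- tree$node.label
  if (is.null(labels)) labels <- rep(NA_character_, nn)
  parts <- strsplit(labels, "/", fixed = TRUE)
  num <- function(p, i) suppressWarnings(as.numeric(p[i]))
  data.frame(
    node = nt + seq_len(nn),
    alrt = vapply(parts, num, numeric(1), 1),
    ufboot = vapply(parts, num, numeric(1), 2)
  )
}
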