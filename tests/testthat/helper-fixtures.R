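# Shared fixtures, generated once per test session and cached.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, fn(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# a small two-clade community exercising every planted feature
tiny_community <- function() {
  memo("tiny", function() {
    cfg <- community_config(
      seed = 7,
      clades = data.frame(clade = c("cladeA", "cladeB"),
                          n_genomes = c(2L, 2L),
                          len_min = 50e3, len_max = 80e3,
                          gc = c(0.40, 0.50)),
      singleton_families = 0L)
    generate_community(cfg)
  })
}

# a mid-size community with high planted prediction-error rates
mid_community <- function() {
  memo("mid", function() {
    cfg <- community_config(
      seed = 11,
      clades = data.frame(clade = c("cladeA", "cladeB"),
                          n_genomes = c(3L, 3L),
                          len_min = 60e3, len_max = 120e3,
                          gc = c(0.40, 0.50)),
      prediction_error_rates = c(fusion = 0.5, spurious = 0.5))
    generate_community(cfg)
  })
}

# truth exon table of a community in gene-model form
truth_models <- function(comm) {
  m <- comm$truth$genes[, c("gene_id", "contig_id", "strand",
                            "start", "end")]
  m$source <- "truth"
  m
}

# extracted introns of a community, annotated with genome and truth kind
truth_introns_extracted <- function(comm) {
  ii <- extract_introns(truth_models(comm), comm$sequences)
  ii$genome_id <- comm$contigs$genome_id[match(ii$contig_id,
                                               comm$contigs$contig_id)]
  tr <- comm$truth$introns
  key <- paste(tr$contig_id, tr$start, tr$end)
  m <- match(paste(ii$contig_id, ii$start, ii$end), key)
  ii$kind <- tr$kind[m]
  ii$truth_class <- tr$class[m]
  ii$has_motif <- tr$has_motif[m]
  ii
}

# independent re-derivation of RED straight from its definition, used as
# the oracle for compute_red
brute_force_red <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen <- rep(NA_real_, nn)
  elen[tree$edge[, 2]] <- tree$edge.length
  desc_leaves <- function(v) {
    if (v <= nt) return(v)
    unlist(lapply(tree$edge[tree$edge[, 1] == v, 2], desc_leaves))
  }
  depth <- function(v) {
    d <- 0
    while (!is.na(parent[v])) {
      d <- d + elen[v]
      v <- parent[v]
    }
    d
  }
  red <- rep(NA_real_, nn)
  red[nt + 1] <- 0
  repeat {
    progressed <- FALSE
    for (v in seq_len(nn)) {
      if (!is.na(red[v]) || is.na(parent[v]) || is.na(red[parent[v]]))
        next
      if (v <= nt) {
        red[v] <- 1
      } else {
        lv <- desc_leaves(v)
        b <- mean(vapply(lv, depth, numeric(1))) - depth(v)
        a <- elen[v]
        red[v] <- red[parent[v]] + a / (a + b) * (1 - red[parent[v]])
      }
      progressed <- TRUE
    }
    if (!anyNA(red) || !progressed) break
  }
  red
}

# closed-form 2x2 Pearson chi-squared: n (ad - bc)^2 / (r1 r2 c1 c2)
chi2_2x2_closed_form <- function(m) {
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# random nucleotide string helper for alignment tests
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
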