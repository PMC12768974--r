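#' Reverse complement of a nucleotide string
#'
#' Plain-character reverse complement over the A/C/G/T/N alphabet, used
#' where sequences are handled as ordinary character vectors rather than
#' `Biostrings` objects.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    chartr("ACGTNacgtn", "TGCANtgcan",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# stable 32-bit polynomial hash of a string; used to derive per-genome
# RNG substreams from the single community seed
stable_hash <- function(x) {
  h <- 0
  for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

derive_seed <- function(root_seed, id) {
  as.integer((as.numeric(root_seed) * 7919 + stable_hash(id)) %% 2147483647)
}

# random nucleotide string with a given GC fraction
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# random codon string (length 3*n) free of stop codons, for planting ORFs
random_codons <- function(n_codons, gc = 0.5) {
  stops <- c("TAA", "TAG", "TGA")
  out <- character(n_codons)
  i <- 1L
  while (i <= n_codons) {
    cod <- random_dna(3, gc)
    if (!(cod %in% stops) && !grepl("N", cod)) {
      out[i] <- cod
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Expand an IUPAC motif to a regular expression
#'
#' @param motif IUPAC nucleotide string (e.g. `"WCTAAC"`).
#' @return single regular-expression string matching the motif.
#' @export
iupac_to_regex <- function(motif) {
  map <- c(A = "A", C = "C", G = "G", T = "T", U = "T",
           R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
           K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
           H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s): ", paste(bad, collapse = ", "))
  paste(map[chars], collapse = "")
}

# draw one concrete sequence matching an IUPAC motif
iupac_instance <- function(motif) {
  map <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))
  chars <- strsplit(toupper(motif), "", fixed = TRUE)[[1]]
  paste(vapply(chars, function(ch) sample(map[[ch]], 1), character(1)),
        collapse = "")
}

# check that a data frame has the required columns
check_columns <- function(df, cols, what = "table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  invisible(df)
}
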