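#' Relative evolutionary divergence (RED) of every node
#'
#' RED normalizes node depth to `[0, 1]` on a rooted tree: the root has
#' RED 0, leaves have RED 1, and an internal node with parent RED `P`,
#' parent branch length `a` and mean distance `b` to its descendant
#' leaves gets `P + a / (a + b) * (1 - P)`. RED is non-decreasing from
#' the root to every leaf. Internal nodes whose subtree has zero total
#' path length inherit the parent's RED with a warning.
#'
#' @param tree `ape::phylo` with non-negative branch lengths,
#'   interpreted as rooted at its root node (a basal multifurcation is
#'   treated as a genuine rooted polytomy).
#' @return data frame `node` (ape node number), `red`, `is_leaf`,
#'   `label` (leaf label or `NA`).
#' @export
compute_red <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  root <- nt + 1L
  # mean distance from each node to its descendant leaves (postorder)
  po <- ape::reorder.phylo(tree, "postorder")
  n_leaves <- rep(0, nn); sum_dist <- rep(0, nn)
  n_leaves[seq_len(nt)] <- 1
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c <- po$edge[i, 2]; len <- po$edge.length[i]
    n_leaves[p] <- n_leaves[p] + n_leaves[c]
    sum_dist[p] <- sum_dist[p] + sum_dist[c] + len * n_leaves[c]
  }
  mean_dist <- sum_dist / n_leaves
  # preorder propagation of RED
  red <- rep(NA_real_, nn)
  red[root] <- 0
  pr <- ape::reorder.phylo(tree, "cladewise")
  warned <- FALSE
  for (i in seq_len(nrow(pr$edge))) {
    p <- pr$edge[i, 1]; c <- pr$edge[i, 2]; a <- pr$edge.length[i]
    if (c <= nt) { red[c] <- 1; next }
    denom <- a + mean_dist[c]
    if (denom <= 0) {
      if (!warned) {
        warning("internal node with zero-length path to all leaves; ",
                "propagating parent RED")
        warned <- TRUE
      }
      red[c] <- red[p]
    } else {
      red[c] <- red[p] + a / denom * (1 - red[p])
    }
  }
  data.frame(node = seq_len(nn), red = red, is_leaf = seq_len(nn) <= nt,
             label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
             stringsAsFactors = FALSE)
}

# canonical key of the unrooted split defined by a clade's leaf set
split_key <- function(leafset, all_leaves) {
  comp <- setdiff(all_leaves, leafset)
  side <- if (length(leafset) < length(comp)) leafset
  else if (length(comp) < length(leafset)) comp
  else {
    a <- paste(sort(leafset), collapse = "|")
    b <- paste(sort(comp), collapse = "|")
    if (a <= b) leafset else comp
  }
  paste(sort(side), collapse = "|")
}

# leaf sets of every node of a rooted tree
node_clades <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  clades <- vector("list", nn)
  for (i in seq_len(nt)) clades[[i]] <- tree$tip.label[i]
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1]; c <- po$edge[i, 2]
    clades[[p]] <- c(clades[[p]], clades[[c]])
  }
  clades
}

#' Default candidate rooting positions
#'
#' Edges incident to the root's children plus basal bipartitions holding
#' at least `min_frac` of the leaves; returned as the child-node numbers
#' of the edges to be midpoint-rerooted.
#'
#' @param tree rooted `ape::phylo`.
#' @param min_frac minimum leaf fraction of a basal bipartition.
#' @return integer vector of node numbers.
#' @export
default_candidate_roots <- function(tree, min_frac = 0.05) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  grand <- tree$edge[tree$edge[, 1] %in% kids, 2]
  clades <- node_clades(tree)
  sizes <- lengths(clades)
  grand <- grand[sizes[grand] >= min_frac * nt & grand > nt]
  sort(unique(c(kids, grand)))
}

#' RED averaged over multiple rooting positions
#'
#' Recomputes RED after rerooting the tree at the midpoint of the parent
#' edge of every candidate node, then averages values per node of the
#' reference rooting (the input tree), matching nodes across rootings by
#' their unrooted bipartition. Nodes absent from some rootings (the
#' endpoints of the rooting edges) are averaged over the rootings where
#' they exist and flagged.
#'
#' @param tree rooted `ape::phylo` (the reference rooting).
#' @param candidate_roots node numbers whose parent edges are used as
#'   rooting positions; defaults to [default_candidate_roots()].
#' @return data frame as [compute_red()] plus `n_rootings` and `flagged`
#'   columns; `red` is the per-node mean.
#' @export
average_red <- function(tree, candidate_roots = NULL) {
  if (is.null(candidate_roots)) candidate_roots <- default_candidate_roots(tree)
  if (length(candidate_roots) == 0) stop("empty candidate root set")
  candidate_roots <- sort(unique(candidate_roots))
  nt <- ape::Ntip(tree)
  all_leaves <- tree$tip.label
  ref_clades <- node_clades(tree)
  ref_keys <- vapply(ref_clades, split_key, character(1),
                     all_leaves = all_leaves)
  acc <- list()
  for (node in candidate_roots) {
    edge_idx <- which(tree$edge[, 2] == node)
    if (length(edge_idx) != 1) stop("candidate root ", node,
                                    " has no parent edge")
    elen <- tree$edge.length[edge_idx]
    rooted <- phytools::reroot(tree, node, position = elen / 2)
    red_r <- compute_red(rooted)
    keys_r <- vapply(node_clades(rooted), split_key, character(1),
                     all_leaves = all_leaves)
    # one value per split per rooting (root-adjacent duplicates averaged)
    vals <- tapply(red_r$red, keys_r, mean)
    acc[[length(acc) + 1]] <- vals
  }
  n_root <- length(acc)
  red_mean <- numeric(length(ref_keys))
  n_obs <- integer(length(ref_keys))
  for (i in seq_along(ref_keys)) {
    v <- vapply(acc, function(a) {
      x <- a[ref_keys[i]]
      if (is.na(x)) NA_real_ else as.numeric(x)
    }, numeric(1))
    red_mean[i] <- mean(v, na.rm = TRUE)
    n_obs[i] <- sum(!is.na(v))
  }
  out <- compute_red(tree)
  out$red <- red_mean
  out$red[out$is_leaf] <- 1
  out$red[nt + 1L] <- 0
  out$n_rootings <- n_obs
  out$flagged <- n_obs < n_root
  out
}

#' Delineate taxonomic ranks from RED values
#'
#' Every leaf is assigned to the order defined by its most recent
#' ancestor with RED strictly below `order_max`, and to the family
#' defined by its most recent ancestor with RED strictly below
#' `family_max`. Leaves that share the defining node share the rank;
#' leaves whose family contains no other leaf (including leaves with no
#' qualifying ancestor at all) are flagged as singleton families.
#'
#' @param tree rooted `ape::phylo`.
#' @param red RED table from [compute_red()] or [average_red()].
#' @param order_max,family_max RED thresholds (strict; defaults 0.22 and
#'   0.65).
#' @return data frame `genome_id`, `order`, `family`,
#'   `singleton_family`; order and family labels are `O<n>` / `F<n>`
#'   keyed to the defining nodes.
#' @export
delineate_ranks <- function(tree, red, order_max = 0.22, family_max = 0.65) {
  nt <- ape::Ntip(tree)
  parent <- rep(NA_integer_, nt + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  red_v <- red$red[order(red$node)]
  anchor <- function(leaf, thresh) {
    v <- parent[leaf]
    while (!is.na(v)) {
      if (red_v[v] < thresh) return(v)
      v <- parent[v]
    }
    NA_integer_
  }
  ord_node <- vapply(seq_len(nt), anchor, integer(1), thresh = order_max)
  fam_node <- vapply(seq_len(nt), anchor, integer(1), thresh = family_max)
  fam_key <- ifelse(is.na(fam_node), paste0("leaf", seq_len(nt)),
                    paste0("node", fam_node))
  ord_key <- ifelse(is.na(ord_node), paste0("leaf", seq_len(nt)),
                    paste0("node", ord_node))
  ord_lab <- setNames(paste0("O", seq_along(unique(ord_key))),
                      unique(ord_key))
  fam_lab <- setNames(paste0("F", seq_along(unique(fam_key))),
                      unique(fam_key))
  fam_sizes <- table(fam_key)
  data.frame(
    genome_id = tree$tip.label,
    order = unname(ord_lab[ord_key]),
    family = unname(fam_lab[fam_key]),
    singleton_family = as.integer(fam_sizes[fam_key]) == 1L,
    stringsAsFactors = FALSE)
}

#' Node support classification from dual supports
#'
#' A node is strongly supported when SH-like aLRT is at least `alrt_min`
#' *and* UFBoot is at least `ufboot_min`; moderately supported when
#' exactly one cut-off is met; poorly supported otherwise. Missing
#' values count as an unmet cut-off.
#'
#' @param alrt,ufboot numeric vectors of supports in percent.
#' @param alrt_min,ufboot_min cut-offs (defaults 80 and 95, inclusive).
#' @return character vector in `{strong, moderate, poor}` with a
#'   `missing` attribute flagging incomplete supports.
#' @export
support_class <- function(alrt, ufboot, alrt_min = 80, ufboot_min = 95) {
  miss <- is.na(alrt) | is.na(ufboot)
  a <- !is.na(alrt) & alrt >= alrt_min
  u <- !is.na(ufboot) & ufboot >= ufboot_min
  out <- ifelse(a & u, "strong", ifelse(xor(a, u), "moderate", "poor"))
  out[miss] <- "poor"
  attr(out, "missing") <- miss
  out
}

#' Congruence of two trees as Pearson correlation of patristic distances
#'
#' @param tree_a,tree_b `ape::phylo` objects sharing at least four
#'   leaves.
#' @return Pearson correlation coefficient over all shared leaf pairs'
#'   path-length distances.
#' @export
tree_congruence <- function(tree_a, tree_b) {
  shared <- intersect(tree_a$tip.label, tree_b$tip.label)
  if (length(shared) < 4) stop("fewer than 4 shared leaves")
  da <- ape::cophenetic.phylo(tree_a)[shared, shared]
  db <- ape::cophenetic.phylo(tree_b)[shared, shared]
  lt <- lower.tri(da)
  cor(da[lt], db[lt])
}

#' Classify metagenomic marker hits at the order level
#'
#' A query is linked to the order of its best genomic-database hit when
#' the hit reaches `id_min` percent identity *and* `bitscore_min`;
#' otherwise it is too distant from the genomic database and labelled
#' `DISTANT`. Queries failing the e-value cut-off are dropped upstream.
#'
#' @param hits best-hit table with `pident`, `bitscore`, `evalue` and
#'   `subject_order` columns; one row per query.
#' @param queries optional character vector of all query ids; queries
#'   without hits are reported as `DISTANT`.
#' @param id_min,bitscore_min,evalue_max thresholds (identity and
#'   bitscore inclusive, e-value inclusive upper bound).
#' @return data frame `query`, `order`.
#' @export
classify_marker_hits <- function(hits, queries = NULL, id_min = 50,
                                 bitscore_min = 100, evalue_max = 1e-5) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  lab <- ifelse(hits$pident >= id_min & hits$bitscore >= bitscore_min,
                hits$subject_order, "DISTANT")
  out <- data.frame(query = hits$query, order = lab,
                    stringsAsFactors = FALSE)
  if (!is.null(queries)) {
    missing <- setdiff(queries, out$query)
    if (length(missing) > 0)
      out <- rbind(out, data.frame(query = missing, order = "DISTANT",
                                   stringsAsFactors = FALSE))
    out <- out[match(queries, out$query), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
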