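## Phylogenomic characterization: lineage specificity via the clade F1
## score, phylogenetic conservation via consenTRAIT, and the paired
## known-vs-unknown conservation comparison.

.rank_letters <- c(d = "domain", p = "phylum", c = "class", o = "order",
                   f = "family", g = "genus", s = "species")

## tip-id sets per node (tips and internal), postorder
.node_tipsets <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  sets <- vector("list", nt + nn)
  for (i in seq_len(nt)) sets[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    p <- ord$edge[k, 1]; ch <- ord$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Lineage specificity of a gene cluster via the clade F1 score
#'
#' For every internal node, recall is the fraction of the clade's genomes
#' carrying the cluster and precision the fraction of carrier genomes
#' falling inside the clade; F1 is their harmonic mean. The best node is
#' the F1 argmax (ties prefer the deeper node, then the larger clade). The
#' cluster is lineage-specific when best F1 > `min_f1`, it occurs in at
#' least `min_genomes` genomes, and its prevalence is below
#' `max_prevalence` of all genomes.
#'
#' @param tree Rooted `phylo` tree; tip labels = genome ids; internal node
#'   labels may carry rank prefixes (`p__`, `c__`, ...).
#' @param presence Character vector of genome ids carrying the cluster.
#' @param min_f1,min_genomes,max_prevalence Lineage-specificity rule
#'   (defaults 0.95, 2, 0.5).
#' @return List: `best_node` (internal node id), `best_f1`, `rank` (rank of
#'   the nearest labelled ancestor), `clade_tips`, `is_lineage_specific`.
#' @export
lineage_f1 <- function(tree, presence, min_f1 = 0.95, min_genomes = 2L,
                       max_prevalence = 0.5) {
  stopifnot(length(presence) >= 1)
  nt <- length(tree$tip.label)
  miss <- setdiff(presence, tree$tip.label)
  if (length(miss)) stop("presence genome not in tree: ", miss[1])
  pres_idx <- match(presence, tree$tip.label)
  sets <- .node_tipsets(tree)
  depths <- ape::node.depth.edgelength(tree)
  nodes <- (nt + 1):(nt + tree$Nnode)
  f1 <- vapply(nodes, function(nd) {
    tp <- sets[[nd]]
    inter <- sum(tp %in% pres_idx)
    if (inter == 0) return(0)
    r <- inter / length(tp)
    p <- inter / length(pres_idx)
    2 * p * r / (p + r)
  }, numeric(1))
  ord <- order(-f1, -depths[nodes], -lengths(sets[nodes]))
  best <- nodes[ord[1]]
  best_f1 <- f1[ord[1]]
  ## nearest labelled ancestor-or-self rank
  rank <- NA_character_
  nd <- best
  repeat {
    lab <- if (!is.null(tree$node.label)) tree$node.label[nd - nt] else ""
    if (!is.na(lab) && nzchar(lab) && grepl("^[dpcofgs]__", lab)) {
      rank <- unname(.rank_letters[substr(lab, 1, 1)])
      break
    }
    up <- tree$edge[tree$edge[, 2] == nd, 1]
    if (!length(up)) break
    nd <- up
  }
  list(best_node = best,
       best_f1 = best_f1,
       rank = rank,
       clade_tips = tree$tip.label[sets[[best]]],
       is_lineage_specific = best_f1 > min_f1 &&
         length(presence) >= min_genomes &&
         length(presence) / nt < max_prevalence)
}

#' Phylogenetic conservation (consenTRAIT tau_D) of a binary trait
#'
#' Finds the maximal non-nested clades in which at least `threshold` of
#' the tips carry the trait; each contributes its mean root-to-tip
#' branch-length depth (measured from the clade root). Positive tips not
#' absorbed by any such clade contribute half their terminal branch
#' length. tau_D is the mean contribution.
#'
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param presence Character vector of trait-positive tip labels
#'   (non-empty).
#' @param threshold Minimum positive-tip fraction of an accepted clade
#'   (default 0.9).
#' @return tau_D (>= 0); the per-clade depths are attached as attribute
#'   `"clade_depths"`.
#' @export
consentrait_tau <- function(tree, presence, threshold = 0.9) {
  if (length(presence) == 0) stop("consentrait_tau: empty presence set")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  nt <- length(tree$tip.label)
  pres_idx <- match(presence, tree$tip.label)
  if (anyNA(pres_idx)) stop("presence tip not in tree")
  sets <- .node_tipsets(tree)
  depths <- ape::node.depth.edgelength(tree)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  term_len <- tree$edge.length[match(seq_len(nt), tree$edge[, 2])]
  contrib <- numeric(0)
  walk <- function(nd) {
    if (nd <= nt) {
      if (nd %in% pres_idx)
        contrib <<- c(contrib, term_len[nd] / 2)
      return(invisible())
    }
    tp <- sets[[nd]]
    frac <- sum(tp %in% pres_idx) / length(tp)
    if (frac >= threshold && length(tp) >= 2) {
      contrib <<- c(contrib, mean(depths[tp] - depths[nd]))
    } else {
      for (ch in children[[as.character(nd)]]) walk(ch)
    }
    invisible()
  }
  walk(nt + 1L)
  tau <- if (length(contrib)) mean(contrib) else 0
  attr(tau, "clade_depths") <- contrib
  tau
}

#' Compare phylogenetic conservation of known vs unknown clusters
#'
#' Wilcoxon signed-rank (paired) test on tau_D values, pairing known and
#' unknown clusters by rank within each lineage-specificity stratum (the
#' i-th largest known tau_D in a stratum is paired with the i-th largest
#' unknown one; the excess of the larger group is dropped).
#'
#' @param tau Numeric vector of tau_D values.
#' @param is_known Logical: TRUE for K/KWP clusters, FALSE for GU/EU.
#' @param stratum Factor-like vector (e.g. lineage-specific yes/no).
#' @return List: `statistic`, `p_value`, `n_pairs`, `median_known`,
#'   `median_unknown`, `direction`.
#' @export
compare_conservation <- function(tau, is_known,
                                 stratum = rep(1L, length(tau))) {
  stopifnot(length(tau) == length(is_known),
            any(is_known), any(!is_known))
  xk <- numeric(0); xu <- numeric(0)
  for (s in unique(stratum)) {
    k <- sort(tau[is_known & stratum == s], decreasing = TRUE)
    u <- sort(tau[!is_known & stratum == s], decreasing = TRUE)
    n <- min(length(k), length(u))
    xk <- c(xk, k[seq_len(n)]); xu <- c(xu, u[seq_len(n)])
  }
  if (length(xk) < 2) stop("compare_conservation: fewer than 2 pairs")
  if (all(xk == xu)) {
    warning("all paired values tied; p = 1")
    return(list(statistic = 0, p_value = 1, n_pairs = length(xk),
                median_known = median(xk), median_unknown = median(xu),
                direction = "tied"))
  }
  wt <- suppressWarnings(wilcox.test(xk, xu, paired = TRUE, exact = FALSE))
  mk <- median(xk); mu <- median(xu)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_pairs = length(xk), median_known = mk, median_unknown = mu,
       direction = if (mu > mk) "unknown > known"
                   else if (mk > mu) "known > unknown" else "tied")
}

#' Remove prophage-only genome presences
#'
#' A genome is dropped from a cluster's presence set when every gene
#' supporting that cluster in that genome lies in a flagged prophage
#' region.
#'
#' @param presence Named list: cluster id -> character vector of genomes.
#' @param gene_map Data frame with columns `gc_id`, `genome`,
#'   `in_prophage` (one row per supporting gene).
#' @return Filtered presence list.
#' @export
exclude_prophage_presence <- function(presence, gene_map) {
  if (is.null(gene_map) || nrow(gene_map) == 0) return(presence)
  all_proph <- tapply(gene_map$in_prophage,
                      list(gene_map$gc_id, gene_map$genome),
                      function(x) all(as.logical(x)))
  for (gc in intersect(names(presence), rownames(all_proph))) {
    drop <- colnames(all_proph)[!is.na(all_proph[gc, ]) & all_proph[gc, ]]
    presence[[gc]] <- setdiff(presence[[gc]], drop)
  }
  presence
}
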