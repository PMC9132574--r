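## Aggregation of gene clusters into gene-cluster communities (GCCs):
## profile-homology graph construction, Markov clustering (MCL), the
## five-metric inflation scan, and the three-pass orphan rescue.

#' Build the profile-homology graph among gene clusters
#'
#' Edges connect cluster pairs with profile probability >= 0.5 and
#' bidirectional coverage > 0.6; the weight is the bitscore / aligned-columns
#' ratio. Reciprocal hits are merged keeping the maximum weight; self-hits
#' are dropped.
#'
#' @param profile_hits Profile-hit data frame (canonical columns).
#' @param min_prob Probability threshold (default 0.5).
#' @param min_cov Bidirectional coverage threshold (default 0.6, strict).
#' @return Undirected weighted `igraph` graph.
#' @export
build_gcc_graph <- function(profile_hits, min_prob = 0.5, min_cov = 0.6) {
  h <- profile_hits
  ok <- h$query_gc != h$target_gc & h$probability >= min_prob &
    h$query_cov > min_cov & h$target_cov > min_cov
  h <- h[ok, , drop = FALSE]
  if (nrow(h) == 0)
    return(igraph::make_empty_graph(0, directed = FALSE))
  w <- h$score / h$aligned_cols
  a <- pmin(h$query_gc, h$target_gc)
  b <- pmax(h$query_gc, h$target_gc)
  key <- paste(a, b, sep = "\r")
  w <- tapply(w, key, max)
  parts <- strsplit(names(w), "\r", fixed = TRUE)
  el <- cbind(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$weight <- as.numeric(w)
  g
}

#' Markov clustering of a weighted graph
#'
#' Column-stochastic flow matrix with self-loops (loop weight = the node's
#' maximum incident edge weight, 1 for isolated nodes), iterating expansion
#' (matrix squaring) then inflation (entrywise power and column
#' renormalization), pruning entries below `pruning`, until the maximum
#' entrywise change drops below `tol` or `max_iter` iterations; communities
#' are read off the attractors of the limit matrix. Isolated nodes become
#' singleton communities.
#'
#' @param graph Undirected weighted `igraph` graph.
#' @param inflation Inflation exponent (> 1).
#' @param pruning Entries below this are zeroed each step (default 1e-5).
#' @param tol Convergence tolerance on the max entry change (default 1e-8).
#' @param max_iter Iteration cap (default 200; hitting it warns and returns
#'   the current interpretation).
#' @return Named integer vector: community id per node.
#' @export
mcl <- function(graph, inflation, pruning = 1e-5, tol = 1e-8,
                max_iter = 200L) {
  stopifnot(inflation > 1)
  n <- igraph::vcount(graph)
  if (n == 0) return(setNames(integer(0), character(0)))
  nm <- igraph::V(graph)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(graph, attr = if (igraph::ecount(graph))
    "weight" else NULL, sparse = FALSE)
  A <- matrix(as.numeric(A), n, n, dimnames = list(nm, nm))
  loop <- apply(A, 1, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2[M2 < pruning] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) break
  }
  if (delta >= tol)
    warning("mcl: not converged after ", max_iter, " iterations")
  .mcl_interpret(M, pruning)
}

## Attractor-based interpretation: attractors are nodes with mass on their
## own diagonal; each attractor's row support forms a community, overlapping
## supports are merged, and stray nodes join the attractor holding most of
## their column mass.
.mcl_interpret <- function(M, pruning = 1e-5) {
  nm <- rownames(M)
  n <- nrow(M)
  attractors <- which(diag(M) > pruning)
  if (length(attractors) == 0) attractors <- seq_len(n)
  memb <- rep(NA_integer_, n)
  next_id <- 0L
  for (a in attractors) {
    support <- unique(c(a, which(M[a, ] > pruning)))
    hit <- unique(memb[support][!is.na(memb[support])])
    if (length(hit) == 0) {
      next_id <- next_id + 1L
      memb[support] <- next_id
    } else {
      keep <- min(hit)
      memb[support] <- keep
      memb[memb %in% setdiff(hit, keep)] <- keep
    }
  }
  for (j in which(is.na(memb))) {
    col <- M[, j]
    col[is.na(memb)] <- 0
    if (max(col) > 0) memb[j] <- memb[which.max(col)]
    else { next_id <- next_id + 1L; memb[j] <- next_id }
  }
  setNames(match(memb, unique(memb)), nm)
}

#' The five community-quality metrics
#'
#' m1: fraction of communities whose members share a single consensus
#' domain architecture; m2: fraction of communities with more than one
#' cluster; m3: fraction of communities whose members' Pfam clans have zero
#' Shannon entropy; m4: mean intra-community edge weight divided by the
#' graph's maximum edge weight; m5: closeness of the community count C to
#' the non-redundant architecture count D, `1 - |C - D| / max(C, D)`. m1
#' and m3 need architectures/clans and are NA without them.
#'
#' @param partition Named community vector (as from [mcl()]).
#' @param graph The weighted graph the partition was computed on.
#' @param consensus_das Named list of domain-token vectors per cluster
#'   (NULL to skip m1/m3).
#' @param clan_map Domain -> clan map for m3.
#' @param n_das Non-redundant architecture count for m5 (NULL to skip).
#' @return Named numeric vector `m1..m5` (NA where unavailable).
#' @export
community_metrics <- function(partition, graph, consensus_das = NULL,
                              clan_map = character(0), n_das = NULL) {
  comms <- split(names(partition), partition)
  C <- length(comms)
  m2 <- mean(lengths(comms) > 1)
  m1 <- m3 <- NA_real_
  if (!is.null(consensus_das) && length(consensus_das)) {
    das <- vapply(names(partition), function(id)
      if (!is.null(consensus_das[[id]]))
        paste(consensus_das[[id]], collapse = "|") else NA_character_,
      character(1))
    single_da <- vapply(comms, function(m) {
      d <- das[m]; d <- d[!is.na(d)]
      length(d) > 0 && length(unique(d)) == 1
    }, logical(1))
    m1 <- mean(single_da)
    clan0 <- vapply(comms, function(m) {
      doms <- unlist(lapply(m, function(id) consensus_das[[id]]))
      if (is.null(doms) || !length(doms)) return(NA)
      annotation_entropy(canonical_tokens(doms, clan_map)) == 0
    }, logical(1))
    m3 <- mean(clan0, na.rm = TRUE)
  }
  wmax <- if (igraph::ecount(graph)) max(igraph::E(graph)$weight) else NA
  m4 <- if (is.na(wmax) || wmax == 0) NA_real_ else {
    el <- igraph::as_edgelist(graph)
    intra <- partition[el[, 1]] == partition[el[, 2]]
    if (!any(intra)) 0 else mean(igraph::E(graph)$weight[intra]) / wmax
  }
  m5 <- if (is.null(n_das) || n_das == 0) NA_real_
        else 1 - abs(C - n_das) / max(C, n_das)
  c(m1 = m1, m2 = m2, m3 = m3, m4 = unname(m4), m5 = m5)
}

#' Scan the MCL inflation grid and pick the best value
#'
#' Runs [mcl()] at every grid value, scores each partition by the
#' unweighted mean of the available metrics, and returns the argmax;
#' ties break toward the smaller inflation.
#'
#' @param graph Weighted graph.
#' @param consensus_das,clan_map,n_das Passed to [community_metrics()].
#' @param grid Inflation values (default `seq(1.2, 3.0, 0.1)`).
#' @param ... Passed to [mcl()].
#' @return List with `inflation`, `partition`, and `scan` (a data frame of
#'   inflation, the five metrics and the composite).
#' @export
select_inflation <- function(graph, consensus_das = NULL,
                             clan_map = character(0), n_das = NULL,
                             grid = seq(1.2, 3.0, by = 0.1), ...) {
  stopifnot(length(grid) >= 1)
  rows <- vector("list", length(grid))
  parts <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    p <- mcl(graph, grid[i], ...)
    m <- community_metrics(p, graph, consensus_das, clan_map, n_das)
    rows[[i]] <- data.frame(inflation = grid[i], t(m),
                            composite = mean(m, na.rm = TRUE),
                            n_communities = length(unique(p)))
    parts[[i]] <- p
  }
  scan <- do.call(rbind, rows)
  best <- which(scan$composite >= max(scan$composite) - 1e-12)[1]
  list(inflation = grid[best], partition = parts[[best]], scan = scan)
}

#' Rescue orphan clusters into existing communities
#'
#' Clusters absent from the graph (their hits failed the strict edge
#' thresholds) are assigned in three passes: (1) each orphan joins the
#' community of its best qualifying hit under relaxed thresholds
#' (probability >= 0.5, both coverages >= 0.4); (2) one more pass against
#' the updated assignment catches orphans whose only links are to
#' just-assigned orphans; (3) the rest become new singleton communities.
#' Already-assigned clusters are never reassigned.
#'
#' @param partition Named community vector over the graph's clusters.
#' @param all_ids All cluster ids of the category (orphans = not in
#'   `partition`).
#' @param profile_hits Full profile-hit table (before edge filtering).
#' @param min_prob,min_cov Relaxed thresholds (defaults 0.5 and 0.4,
#'   coverage inclusive).
#' @return Extended named community vector covering `all_ids`.
#' @export
assign_orphans <- function(partition, all_ids, profile_hits,
                           min_prob = 0.5, min_cov = 0.4) {
  orphans <- setdiff(all_ids, names(partition))
  if (length(orphans) == 0) return(partition)
  h <- profile_hits[, .hit_columns$profile, drop = FALSE]
  ok <- h$query_gc != h$target_gc & h$probability >= min_prob &
    h$query_cov >= min_cov & h$target_cov >= min_cov
  h <- h[ok, , drop = FALSE]
  h <- rbind(h, data.frame(query_gc = h$target_gc, target_gc = h$query_gc,
                           probability = h$probability, score = h$score,
                           aligned_cols = h$aligned_cols,
                           query_cov = h$target_cov,
                           target_cov = h$query_cov))
  w <- h$score / h$aligned_cols
  for (pass in 1:2) {
    assigned_now <- character(0)
    for (o in setdiff(orphans, names(partition))) {
      cand <- which(h$query_gc == o & h$target_gc %in% names(partition))
      if (!length(cand)) next
      best <- cand[order(-h$probability[cand], -w[cand])][1]
      partition[o] <- partition[[h$target_gc[best]]]
      assigned_now <- c(assigned_now, o)
    }
    if (!length(assigned_now)) break
  }
  left <- setdiff(orphans, names(partition))
  if (length(left)) {
    base <- if (length(partition)) max(partition) else 0L
    partition[left] <- base + seq_along(left)
  }
  partition
}

#' Infer gene-cluster communities for every category
#'
#' The Known category is processed first with the full inflation scan; its
#' best inflation is reused for KWP, GU and EU. Each category then goes
#' through orphan rescue, so every cluster ends in exactly one community.
#'
#' @param cluster_ids Named list of character vectors: cluster ids per
#'   category (names among K, KWP, GU, EU; K required when others present).
#' @param profile_hits Named list of profile-hit data frames per category.
#' @param consensus_das,clan_map,n_das Passed to the Known scan metrics.
#' @param grid Inflation grid for the Known scan.
#' @return List per category: `partition`, `inflation`; plus `scan` for K.
#' @export
infer_communities <- function(cluster_ids, profile_hits,
                              consensus_das = NULL, clan_map = character(0),
                              n_das = NULL, grid = seq(1.2, 3.0, by = 0.1)) {
  res <- list()
  infl <- NULL
  cats <- intersect(c("K", "KWP", "GU", "EU"), names(cluster_ids))
  for (cat in cats) {
    hits <- profile_hits[[cat]]
    if (is.null(hits)) hits <- .empty_profile_hits()
    g <- build_gcc_graph(hits)
    if (cat == "K") {
      if (igraph::vcount(g) > 0) {
        sel <- select_inflation(g, consensus_das, clan_map, n_das, grid)
        infl <- sel$inflation
        part <- sel$partition
        res$K <- list(scan = sel$scan)
      } else {
        infl <- grid[1]
        part <- setNames(integer(0), character(0))
        res$K <- list(scan = NULL)
      }
    } else {
      if (is.null(infl)) infl <- grid[1]
      part <- if (igraph::vcount(g) > 0) mcl(g, infl)
              else setNames(integer(0), character(0))
    }
    part <- assign_orphans(part, cluster_ids[[cat]], hits)
    res[[cat]]$partition <- part
    res[[cat]]$inflation <- infl
  }
  res
}

.empty_profile_hits <- function() {
  data.frame(query_gc = character(0), target_gc = character(0),
             probability = numeric(0), score = numeric(0),
             aligned_cols = integer(0), query_cov = numeric(0),
             target_cov = numeric(0))
}
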