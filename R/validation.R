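## Intra-cluster compositional validation: size flagging, SSN-based
## representative selection, MSA outlier screening, broken-stick thresholds,
## shadow/spurious filtering, and the keep/discard decision.

#' Broken-stick threshold over a vector of non-negative values
#'
#' Sorts the value shares in decreasing order and compares each share to the
#' broken-stick null expectation `E_k = (1/N) * sum_{i=k..N} 1/i`. The
#' threshold is the smallest value whose share still strictly exceeds its
#' expectation; 0 when no share exceeds expectation. This is the
#' deterministic closed form; a resampling variant that averages over random
#' subsets is available via `n_iter > 0` and must agree with the closed form
#' within one rank on any reasonable input.
#'
#' @param values Non-negative numeric vector, length >= 2, not all zero.
#' @param n_iter If > 0, number of random-subset resampling iterations; the
#'   expectations are then averaged over subsets of the data.
#' @param seed Seed for the resampling variant.
#' @return The threshold, on the scale of `values`.
#' @export
broken_stick_threshold <- function(values, n_iter = 0, seed = 1L) {
  stopifnot(length(values) >= 2, all(values >= 0))
  if (sum(values) == 0) stop("broken_stick_threshold: all-zero input")
  n <- length(values)
  ord <- order(values, decreasing = TRUE)
  shares <- values[ord] / sum(values)
  expect_k <- function(nn) rev(cumsum(1 / rev(seq_len(nn)))) / nn
  closed_form_rank <- function(v) {
    sh <- sort(v, decreasing = TRUE) / sum(v)
    exceeds <- sh > expect_k(length(v)) + 1e-12
    if (!any(exceeds)) 0L else max(which(exceeds))
  }
  if (n_iter > 0) {
    ## resampling variant: random 80% subsets (without replacement), the
    ## closed-form cut rank of each subset mapped back to the full ordering
    ## via the threshold value, averaged over iterations
    old <- .save_seed(); on.exit(.restore_seed(old))
    set.seed(seed)
    sorted <- values[ord]
    m <- max(2L, ceiling(0.8 * n))
    ranks <- vapply(seq_len(n_iter), function(i) {
      sub <- sample(values, m)
      k <- closed_form_rank(sub)
      if (k == 0L) return(0L)
      thr <- sort(sub, decreasing = TRUE)[k]
      max(which(sorted >= thr))
    }, integer(1))
    k <- as.integer(round(mean(ranks)))
    if (k == 0L) return(0)
    return(values[ord][k])
  }
  k <- closed_form_rank(values)
  if (k == 0L) return(0)
  values[ord][k]
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Flag clusters below a minimum size
#'
#' Flagged clusters bypass validation: they have too few sequences to give
#' reliable intra-cluster statistics.
#'
#' @param clusters A `gc_clusters` object.
#' @param min_size Minimum member count (default 10).
#' @return The clusters with the `flagged` column set.
#' @export
flag_small_clusters <- function(clusters, min_size = 10L) {
  stopifnot(min_size >= 1)
  clusters$flagged <- lengths(clusters$members) < min_size
  clusters
}

#' Default pairwise scorer: semi-global alignment similarity
#'
#' Scores every sequence in `pool` against `subject` with an overlap
#' (semi-global) alignment under BLOSUM62. Scores are clamped at a small
#' positive floor so that downstream graph algorithms (maximum spanning
#' tree, eigenvector centrality) see positive weights.
#'
#' @param pool Character vector of amino-acid sequences.
#' @param subject Single amino-acid sequence.
#' @return Numeric vector of similarity scores, one per `pool` entry.
#' @export
semiglobal_scorer <- function(pool, subject) {
  sc <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(pool), Biostrings::AAString(subject),
    type = "overlap", substitutionMatrix = "BLOSUM62", scoreOnly = TRUE)
  pmax(sc, 1e-6)
}

#' Build the sequence similarity network (SSN) of a cluster
#'
#' Complete weighted graph on the member genes; edge weights come from a
#' symmetric pairwise similarity scorer (higher = more similar).
#'
#' @param genes A `gc_genes` data frame restricted to the cluster members
#'   (>= 2 rows).
#' @param scorer Function `(pool, subject) -> numeric` scoring a vector of
#'   sequences against one; defaults to [semiglobal_scorer()].
#' @return An `igraph` undirected weighted graph with vertex names = gene
#'   ids.
#' @export
build_ssn <- function(genes, scorer = semiglobal_scorer) {
  n <- nrow(genes)
  stopifnot(n >= 2)
  ids <- genes$id
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (j in seq_len(n - 1)) {
    idx <- (j + 1):n
    sc <- tryCatch(scorer(genes$sequence[idx], genes$sequence[j]),
                   error = function(e)
                     stop("scorer failed on pair (", ids[j], ", ",
                          ids[idx[1]], "): ", conditionMessage(e)))
    from <- c(from, rep(j, length(idx))); to <- c(to, idx); w <- c(w, sc)
  }
  g <- igraph::make_graph(rbind(from, to), n = n, directed = FALSE)
  igraph::V(g)$name <- ids
  igraph::E(g)$weight <- w
  g
}

#' Trim an SSN to its strongest connected core
#'
#' Removes low-weight edges while keeping the graph a single connected
#' component spanning all nodes: edges with weight >= `t*` are kept, where
#' `t*` is the largest threshold that leaves one component. `t*` equals the
#' bottleneck (minimum) edge weight of the maximum spanning tree.
#'
#' @param graph Connected `igraph` weighted graph.
#' @return The trimmed subgraph (connected, spans all vertices).
#' @export
trim_ssn <- function(graph) {
  if (!igraph::is_connected(graph)) stop("trim_ssn: graph is disconnected")
  if (igraph::ecount(graph) == 0) return(graph)
  mstg <- igraph::mst(graph, weights = -igraph::E(graph)$weight)
  tstar <- min(igraph::E(graph)$weight[
    igraph::get_edge_ids(graph, t(igraph::as_edgelist(mstg, names = FALSE)))])
  keep <- which(igraph::E(graph)$weight >= tstar)
  igraph::subgraph_from_edges(graph, keep, delete.vertices = FALSE)
}

#' Select the cluster representative from a trimmed SSN
#'
#' The most central node by eigenvector centrality on the weighted graph;
#' ties (within `1e-8`) broken by lexicographically smallest gene id.
#'
#' @param graph Connected weighted `igraph` graph with named vertices.
#' @return The representative gene id.
#' @export
select_representative <- function(graph) {
  n <- igraph::vcount(graph)
  stopifnot(n >= 1)
  if (n == 1) return(igraph::V(graph)$name)
  ec <- igraph::eigen_centrality(
    graph, weights = igraph::E(graph)$weight,
    options = list(maxiter = 10000L, tol = 1e-10))$vector
  top <- max(ec)
  cand <- names(ec)[ec >= top - 1e-8]
  sort(cand)[1]
}

#' Align cluster members with a naive progressive (padding) aligner
#'
#' Adequate for near-identical families without indels (the synthetic
#' fixtures): sequences are right-padded with gaps to equal length. Any
#' external aligner producing a standard multi-FASTA alignment can be used
#' instead; [detect_msa_outliers()] accepts any such alignment.
#'
#' @param sequences Named character vector of amino-acid sequences.
#' @return Named character vector of gapped rows of equal width.
#' @export
align_msa_naive <- function(sequences) {
  w <- max(nchar(sequences))
  pad <- function(s) paste0(s, strrep("-", w - nchar(s)))
  setNames(vapply(sequences, pad, character(1)), names(sequences))
}

#' Detect non-homologous sequences in a cluster alignment
#'
#' Per-sequence distance to the representative = 1 minus the fraction of
#' identical aligned columns (columns where both rows are gaps are ignored).
#' Outliers are sequences whose distance exceeds both the Tukey fence
#' `Q3 + 1.5 IQR` of the distance distribution and a hard floor (default
#' 0.8). The representative is never an outlier; alignments with fewer than
#' 4 sequences return no outliers (the IQR is not meaningful).
#'
#' @param alignment Named character vector of equal-width gapped rows.
#' @param representative Name of the representative row.
#' @param hard_floor Minimum distance an outlier must exceed.
#' @return Character vector of outlier gene ids (possibly empty).
#' @export
detect_msa_outliers <- function(alignment, representative, hard_floor = 0.8) {
  if (!representative %in% names(alignment))
    stop("representative ", representative, " absent from alignment")
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows differ in width")
  if (length(alignment) < 4) return(character(0))
  rep_chars <- strsplit(alignment[[representative]], "")[[1]]
  dist_to_rep <- vapply(alignment, function(row) {
    ch <- strsplit(row, "")[[1]]
    use <- !(ch == "-" & rep_chars == "-")
    if (!any(use)) return(0)
    1 - sum(ch[use] == rep_chars[use] & ch[use] != "-") / sum(use)
  }, numeric(1))
  q <- quantile(dist_to_rep, c(0.25, 0.75), names = FALSE, type = 7)
  fence <- q[2] + 1.5 * (q[2] - q[1])
  out <- names(dist_to_rep)[dist_to_rep > fence & dist_to_rep > hard_floor]
  setdiff(out, representative)
}

#' Flag shadow genes on a contig
#'
#' For every pair of genes on the same contig, the shorter gene is flagged
#' when the pair overlaps by at least `min_opposite` bp on opposite strands,
#' or by at least `min_same_frac` of the shorter gene on the same strand.
#' Length ties flag the gene with the larger start coordinate.
#'
#' @param genes `gc_genes` rows sharing one contig, with `start`, `end`,
#'   `strand` set.
#' @param min_opposite Opposite-strand overlap threshold in bp (default 60).
#' @param min_same_frac Same-strand overlap threshold as a fraction of the
#'   shorter gene (default 0.5).
#' @return Character vector of flagged gene ids.
#' @export
flag_shadow_genes <- function(genes, min_opposite = 60L, min_same_frac = 0.5) {
  n <- nrow(genes)
  if (n < 2) return(character(0))
  flagged <- character(0)
  len <- genes$end - genes$start + 1L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ov <- min(genes$end[i], genes$end[j]) - max(genes$start[i], genes$start[j]) + 1L
    if (ov <= 0) next
    shorter <- min(len[i], len[j])
    hit <- if (genes$strand[i] != genes$strand[j]) ov >= min_opposite
           else ov >= min_same_frac * shorter
    if (hit) {
      k <- if (len[i] < len[j]) i
           else if (len[j] < len[i]) j
           else if (genes$start[i] > genes$start[j]) i else j
      flagged <- c(flagged, genes$id[k])
    }
  }
  unique(flagged)
}

#' Validate all non-flagged clusters
#'
#' Runs the compositional pipeline per cluster — SSN build, trim,
#' representative selection, MSA outlier screen — then applies the global
#' discard rules: a cluster is discarded when its outlier fraction exceeds
#' the broken-stick threshold computed over all clusters' outlier fractions,
#' or when >= `max_shadow` of its members are shadow genes. Kept clusters
#' have their individual shadow, spurious and outlier genes removed.
#'
#' @param clusters A `gc_clusters` object (flag small clusters first).
#' @param genes A `gc_genes` data frame covering all members.
#' @param shadow_ids,spurious_ids Character vectors of flagged gene ids.
#' @param scorer Pairwise scorer for [build_ssn()].
#' @param aligner MSA function, defaults to [align_msa_naive()].
#' @param max_shadow Shadow-gene fraction triggering discard (default 0.30).
#' @param hard_floor Passed to [detect_msa_outliers()].
#' @return List with `clusters` (kept, membership updated, representatives
#'   reassigned) and `report` (one row per validated cluster: outlier and
#'   shadow fractions, decision).
#' @export
validate_clusters <- function(clusters, genes, shadow_ids = character(0),
                              spurious_ids = character(0),
                              scorer = semiglobal_scorer,
                              aligner = align_msa_naive,
                              max_shadow = 0.30, hard_floor = 0.8) {
  seqs <- setNames(genes$sequence, genes$id)
  todo <- which(!clusters$flagged)
  rep_new <- character(length(todo))
  outliers <- vector("list", length(todo))
  out_frac <- numeric(length(todo))
  shad_frac <- numeric(length(todo))
  for (k in seq_along(todo)) {
    i <- todo[k]
    mem <- clusters$members[[i]]
    if (length(mem) >= 2) {
      ssn <- build_ssn(genes[match(mem, genes$id), , drop = FALSE], scorer)
      rep_id <- select_representative(trim_ssn(ssn))
      aln <- aligner(seqs[mem])
      out <- detect_msa_outliers(aln, rep_id, hard_floor = hard_floor)
    } else {
      rep_id <- mem
      out <- character(0)
    }
    rep_new[k] <- rep_id
    outliers[[k]] <- out
    out_frac[k] <- length(out) / length(mem)
    shad_frac[k] <- mean(mem %in% shadow_ids)
  }
  bs <- if (all(out_frac == 0)) 0
        else if (length(out_frac) < 2) Inf   # no distribution to threshold on
        else broken_stick_threshold(out_frac)
  discard <- out_frac > bs | shad_frac >= max_shadow
  report <- data.frame(
    cluster_id = clusters$id[todo], new_representative = rep_new,
    n_outliers = lengths(outliers), outlier_fraction = out_frac,
    shadow_fraction = shad_frac,
    decision = ifelse(discard, "discard", "keep"),
    stringsAsFactors = FALSE)
  report$outlier_genes <- outliers
  kept <- clusters
  kept$category[kept$id %in% report$cluster_id[discard]] <- "DISCARDED"
  for (k in seq_along(todo)) {
    i <- todo[k]
    if (discard[k]) next
    drop <- unique(c(outliers[[k]],
                     intersect(clusters$members[[i]], shadow_ids),
                     intersect(clusters$members[[i]], spurious_ids)))
    mem <- setdiff(clusters$members[[i]], drop)
    if (length(mem) == 0) mem <- rep_new[k]
    if (!rep_new[k] %in% mem) rep_new[k] <- sort(mem)[1]
    kept$members[[i]] <- mem
    kept$representative[i] <- rep_new[k]
  }
  list(clusters = kept, report = report, threshold = bs)
}
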