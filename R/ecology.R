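## Ecological characterization: abundance profiles, sample selection,
## accumulation curves, sample grouping, count-preserving null models and
## the Levins niche-breadth distribution calls.

#' Select samples by gene count
#'
#' Retains samples whose gene count is at least the first quartile of the
#' count distribution (linear-interpolation, type-7 quantile).
#'
#' @param gene_counts Named numeric vector: genes per sample (>= 4).
#' @return Character vector of retained sample names.
#' @export
select_samples <- function(gene_counts) {
  stopifnot(length(gene_counts) >= 4)
  q1 <- quantile(gene_counts, 0.25, names = FALSE, type = 7)
  names(gene_counts)[gene_counts >= q1]
}

#' Gene-cluster abundance matrix from per-gene coverage
#'
#' Gene abundance = summed per-base coverage divided by gene length;
#' cluster abundance = sum over member genes; each sample column is then
#' total-sum scaled to proportions (columns summing to 0 stay 0).
#'
#' @param coverage Data frame with columns `gene_id`, `sample`, `coverage`
#'   (summed per-base read coverage of the gene in the sample).
#' @param gene_lengths Named numeric vector of gene lengths (> 0).
#' @param clusters A `gc_clusters` object.
#' @return Numeric matrix, clusters x samples, columns summing to 1. The
#'   raw (pre-scaling) matrix is attached as attribute `"raw"`.
#' @export
cluster_abundance <- function(coverage, gene_lengths, clusters) {
  if (any(gene_lengths <= 0)) stop("gene with zero length")
  len <- gene_lengths[coverage$gene_id]
  if (anyNA(len)) stop("coverage for gene without a length: ",
                       coverage$gene_id[which(is.na(len))[1]])
  ab <- coverage$coverage / len
  gc_of <- setNames(rep(clusters$id, lengths(clusters$members)),
                    unlist(clusters$members))
  gc <- gc_of[coverage$gene_id]
  keep <- !is.na(gc)
  m <- tapply(ab[keep], list(gc[keep], coverage$sample[keep]), sum,
              default = 0)
  full <- matrix(0, nrow(clusters), length(colnames(m)),
                 dimnames = list(clusters$id, colnames(m)))
  full[rownames(m), ] <- m
  tss <- apply(full, 2, function(col) if (sum(col) > 0) col / sum(col) else col)
  tss <- matrix(tss, nrow(full), ncol(full), dimnames = dimnames(full))
  attr(tss, "raw") <- full
  tss
}

#' Gene-cluster accumulation curve
#'
#' For each sample count k, the mean and standard deviation of the number
#' of distinct clusters recovered over `n_perm` random sample orderings.
#' Optionally removes low-abundance singleton clusters first.
#'
#' @param abundance Clusters x samples matrix (presence = value > 0).
#' @param n_perm Number of random orderings (default 1000).
#' @param seed Random seed.
#' @param singleton_cutoff If not NULL, clusters present in exactly one
#'   sample with total abundance below this cutoff are dropped first.
#' @return Data frame with `n_samples`, `mean_gcs`, `sd_gcs`.
#' @export
accumulation_curve <- function(abundance, n_perm = 1000L, seed = 1L,
                               singleton_cutoff = NULL) {
  stopifnot(n_perm >= 1)
  pres <- abundance > 0
  if (!is.null(singleton_cutoff)) {
    single <- rowSums(pres) == 1
    low <- rowSums(abundance) < singleton_cutoff
    pres <- pres[!(single & low), , drop = FALSE]
  }
  n <- ncol(pres)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  acc <- matrix(0L, n_perm, n)
  for (p in seq_len(n_perm)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, nrow(pres))
    for (k in seq_len(n)) {
      seen <- seen | pres[, ord[k]]
      acc[p, k] <- sum(seen)
    }
  }
  data.frame(n_samples = seq_len(n),
             mean_gcs = colMeans(acc),
             sd_gcs = apply(acc, 2, sd))
}

#' Group samples by gene-cluster content
#'
#' Bray-Curtis dissimilarity between TSS sample profiles, average-linkage
#' hierarchical clustering, and a flat cut at the height maximizing the
#' mean silhouette width over all candidate merge heights; groups smaller
#' than `min_size` are merged into the nearest group by centroid
#' dissimilarity. Degenerate inputs (all-identical samples) give one group.
#'
#' @param abundance Clusters x samples TSS matrix (>= 2 samples).
#' @param min_size Minimum group size before merging (default 3).
#' @return Named integer vector: group id per sample.
#' @export
group_samples <- function(abundance, min_size = 3L) {
  n <- ncol(abundance)
  stopifnot(n >= 2)
  d <- vegan::vegdist(t(abundance), method = "bray")
  dm <- as.matrix(d)
  if (max(d) < 1e-12) return(setNames(rep(1L, n), colnames(abundance)))
  hc <- stats::hclust(d, method = "average")
  heights <- sort(unique(hc$height))
  cuts <- lapply(heights, function(h) stats::cutree(hc, h = h))
  mean_sil <- function(cl) {
    k <- length(unique(cl))
    if (k < 2 || k >= n) return(-Inf)
    s <- vapply(seq_len(n), function(i) {
      own <- cl == cl[i]
      if (sum(own) == 1) return(0)   # silhouette of a singleton is 0
      a <- mean(dm[i, own & seq_len(n) != i])
      b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
        mean(dm[i, cl == g]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }
  sils <- vapply(cuts, mean_sil, numeric(1))
  if (all(!is.finite(sils)))
    return(setNames(rep(1L, n), colnames(abundance)))
  cl <- cuts[[which.max(sils)]]
  ## merge undersized groups into the nearest group by centroid distance
  repeat {
    sizes <- table(cl)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1) break
    g <- small[which.min(sizes[small])]
    idx <- cl == as.integer(g)
    cent <- rowMeans(abundance[, idx, drop = FALSE])
    others <- setdiff(unique(cl), as.integer(g))
    dd <- vapply(others, function(o) {
      co <- rowMeans(abundance[, cl == o, drop = FALSE])
      sum(abs(cent - co)) / sum(cent + co)
    }, numeric(1))
    cl[idx] <- others[which.min(dd)]
  }
  setNames(match(cl, unique(cl)), colnames(abundance))
}

#' Count-preserving (quasiswap-style) null matrices
#'
#' Each null matrix preserves every row and column sum of the input
#' exactly: a random margin-preserving fill (via [stats::r2dtable()]) is
#' followed by repeated random 2x2 swap moves (add `[1,-1;-1,1]` to a
#' random 2x2 submatrix when the result stays non-negative), with at least
#' `10 * fill` attempted moves, where fill is the number of non-zero cells.
#'
#' @param m Non-negative integer matrix.
#' @param n_null Number of null matrices (default 100).
#' @param seed Random seed.
#' @return List of `n_null` matrices with identical margins to `m`.
#' @export
quasiswap_null <- function(m, n_null = 100L, seed = 1L) {
  if (any(m < 0) || any(m != round(m)))
    stop("quasiswap_null: matrix must hold non-negative integers")
  storage.mode(m) <- "integer"
  nr <- nrow(m); nc <- ncol(m)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  if (nr < 2 || nc < 2)
    return(replicate(n_null, m, simplify = FALSE))
  rs <- rowSums(m); cs <- colSums(m)
  n_moves <- max(10L * sum(m > 0), 100L)
  lapply(seq_len(n_null), function(i) {
    x <- r2dtable(1, rs, cs)[[1]]
    rows <- sample.int(nr, n_moves, replace = TRUE)
    rows2 <- sample.int(nr, n_moves, replace = TRUE)
    cols <- sample.int(nc, n_moves, replace = TRUE)
    cols2 <- sample.int(nc, n_moves, replace = TRUE)
    sgn <- sample(c(1L, -1L), n_moves, replace = TRUE)
    for (k in seq_len(n_moves)) {
      r1 <- rows[k]; r2 <- rows2[k]; c1 <- cols[k]; c2 <- cols2[k]
      if (r1 == r2 || c1 == c2) next
      s <- sgn[k]
      if (x[r1, c1] + s < 0 || x[r2, c2] + s < 0 ||
          x[r1, c2] - s < 0 || x[r2, c1] - s < 0) next
      x[r1, c1] <- x[r1, c1] + s; x[r2, c2] <- x[r2, c2] + s
      x[r1, c2] <- x[r1, c2] - s; x[r2, c1] <- x[r2, c1] - s
    }
    dimnames(x) <- dimnames(m)
    x
  })
}

#' Levins niche breadth
#'
#' `B = 1 / sum(p_i^2)` over the proportional abundance of a cluster
#' across samples; ranges from 1 (single-sample occupancy) to the number
#' of samples (uniform spread). Scale-invariant.
#'
#' @param p Non-negative abundance vector with positive sum.
#' @return The niche breadth B.
#' @export
niche_breadth <- function(p) {
  stopifnot(all(p >= 0))
  if (sum(p) == 0) stop("niche_breadth: all-zero abundance row")
  p <- p / sum(p)
  1 / sum(p^2)
}

#' Classify a cluster's environmental distribution
#'
#' Per dataset, the observed niche breadth is compared to the 2.5% and
#' 97.5% quantiles of its null distribution: Narrow below the lower
#' quantile, Broad above the upper, Nonsignificant otherwise. The
#' consensus is the plurality over datasets; ties give Nonsignificant.
#'
#' @param observed Numeric vector: observed B per dataset.
#' @param nulls List of numeric vectors: null Bs per dataset.
#' @return List with `call`, and `votes` (per-dataset calls).
#' @export
classify_distribution <- function(observed, nulls) {
  stopifnot(length(observed) >= 1, length(observed) == length(nulls))
  votes <- vapply(seq_along(observed), function(i) {
    q <- quantile(nulls[[i]], c(0.025, 0.975), names = FALSE, type = 7)
    if (observed[i] < q[1]) "Narrow"
    else if (observed[i] > q[2]) "Broad"
    else "Nonsignificant"
  }, character(1))
  tab <- table(factor(votes, c("Narrow", "Broad", "Nonsignificant")))
  top <- names(tab)[tab == max(tab)]
  call <- if (length(top) > 1) "Nonsignificant" else top
  list(call = call, votes = votes)
}

#' Niche-breadth distribution calls for all clusters
#'
#' The divide-and-conquer workflow: samples are grouped by content
#' ([group_samples()]); `n_datasets` random datasets are drawn by picking
#' one sample per group; each dataset's abundances are rescaled to integer
#' counts and randomized with [quasiswap_null()]; observed vs null niche
#' breadths yield per-dataset calls, combined by majority vote. Clusters
#' with mean relative abundance below `min_abundance` are excluded.
#'
#' @param abundance Clusters x samples TSS matrix.
#' @param n_datasets Random datasets for the vote (default 10).
#' @param n_null Null matrices per dataset (default 100).
#' @param seed Random seed.
#' @param min_abundance Mean relative-abundance floor (default 1e-5).
#' @param groups Optional precomputed sample grouping.
#' @param scale Integer rescaling factor before the null model (default
#'   1e6).
#' @return Data frame: `gc_id`, `call`, `n_narrow`, `n_broad`,
#'   `n_nonsignificant`.
#' @export
distribution_calls <- function(abundance, n_datasets = 10L, n_null = 100L,
                               seed = 1L, min_abundance = 1e-5,
                               groups = NULL, scale = 1e6) {
  keep <- rowMeans(abundance) >= min_abundance
  ab <- abundance[keep, , drop = FALSE]
  if (is.null(groups)) groups <- group_samples(ab)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  gids <- unique(groups)
  votes <- matrix(NA_character_, nrow(ab), n_datasets,
                  dimnames = list(rownames(ab), NULL))
  for (d in seq_len(n_datasets)) {
    pick <- vapply(gids, function(g) {
      s <- names(groups)[groups == g]
      if (length(s) == 1) s else sample(s, 1)
    }, character(1))
    sub <- ab[, pick, drop = FALSE]
    counts <- round(sub * scale)
    nz <- rowSums(counts) > 0
    nulls <- quasiswap_null(counts[nz, , drop = FALSE], n_null = n_null,
                            seed = sample.int(2^31 - 1, 1))
    obs <- apply(counts[nz, , drop = FALSE], 1, niche_breadth)
    nullB <- vapply(nulls, function(x) apply(x, 1, niche_breadth),
                    numeric(sum(nz)))
    if (sum(nz) == 1) nullB <- matrix(nullB, 1, n_null)
    q <- apply(nullB, 1, quantile, probs = c(0.025, 0.975), type = 7)
    v <- ifelse(obs < q[1, ], "Narrow",
                ifelse(obs > q[2, ], "Broad", "Nonsignificant"))
    votes[rownames(counts)[nz], d] <- v
  }
  call_of <- apply(votes, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("Nonsignificant")
    tab <- table(factor(v, c("Narrow", "Broad", "Nonsignificant")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) "Nonsignificant" else top
  })
  data.frame(gc_id = rownames(ab), call = call_of,
             n_narrow = rowSums(votes == "Narrow", na.rm = TRUE),
             n_broad = rowSums(votes == "Broad", na.rm = TRUE),
             n_nonsignificant = rowSums(votes == "Nonsignificant",
                                        na.rm = TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}
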