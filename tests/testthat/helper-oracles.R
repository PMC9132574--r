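## Independent oracles and small fixture builders shared across tests.
## The oracles deliberately re-derive results by brute force or naive
## iteration so they stay independent of the implementation paths they
## check.

## exhaustive threshold oracle: largest edge-weight threshold keeping the
## graph one connected component
oracle_trim_threshold <- function(g) {
  ws <- sort(unique(igraph::E(g)$weight))
  best <- -Inf
  for (t in ws) {
    sub <- igraph::subgraph_from_edges(g, which(igraph::E(g)$weight >= t),
                                       delete.vertices = FALSE)
    if (igraph::is_connected(sub)) best <- max(best, t)
  }
  best
}

## naive dense MCL oracle: no pruning, support-component interpretation
oracle_mcl <- function(g, r, iters = 500L) {
  n <- igraph::vcount(g)
  A <- igraph::as_adjacency_matrix(
    g, attr = if (igraph::ecount(g)) "weight" else NULL, sparse = FALSE)
  A <- matrix(as.numeric(A), n, n)
  loop <- apply(A, 1, max); loop[loop == 0] <- 1; diag(A) <- loop
  M <- sweep(A, 2, colSums(A), "/")
  for (i in seq_len(iters)) {
    M2 <- M %*% M
    M2 <- M2^r
    M2 <- sweep(M2, 2, colSums(M2), "/")
    done <- max(abs(M2 - M)) < 1e-10
    M <- M2
    if (done) break
  }
  S <- (M > 1e-6) | t(M > 1e-6)
  gg <- igraph::graph_from_adjacency_matrix(S, mode = "undirected",
                                            diag = FALSE)
  igraph::components(gg)$membership
}

## canonical string form of a set partition (ignores label permutation)
canon_partition <- function(p) {
  u <- split(seq_along(p), p)
  paste(sort(vapply(u, function(x) paste(sort(x), collapse = ","), "")),
        collapse = ";")
}

## adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - e
  if (denom == 0) return(1)
  (sij - e) / denom
}

## random connected weighted graph with <= n_max nodes
random_connected_graph <- function(seed, n_max = 8L) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  repeat {
    g <- igraph::sample_gnp(n, 0.6)
    if (igraph::is_connected(g) && igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- round(runif(igraph::ecount(g), 0.1, 5), 2)
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

## tiny gc_genes data frame from named sequences
make_genes <- function(seqs, complete = TRUE) {
  g <- data.frame(id = names(seqs), sequence = unname(seqs),
                  is_complete = rep_len(complete, length(seqs)),
                  origin = "test", contig = names(seqs), start = 1L,
                  end = nchar(seqs) * 3L, strand = "+", flags = "",
                  stringsAsFactors = FALSE)
  class(g) <- c("gc_genes", "data.frame")
  g
}

random_aa <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aa, n, TRUE), collapse = "")
}
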