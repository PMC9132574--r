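## Domain-annotation homogeneity of clusters: w-shingling of domain
## architectures, clan-aware Jaccard similarity, and annotation-frequency
## Shannon entropy.

#' Build a gene's domain architecture from its domain hits
#'
#' Tokens are ordered by ascending envelope start. Each token keeps the
#' domain name, its clan (may be empty) and the terminal variant (N/C/M
#' split domains).
#'
#' @param hits Data frame of domain hits for one gene (canonical columns,
#'   see [read_hits()]).
#' @return A data frame of class `domain_architecture` with columns
#'   `domain`, `clan`, `terminal_variant` in architecture order.
#' @export
domain_architecture <- function(hits) {
  stopifnot(nrow(hits) >= 1)
  hits <- hits[order(hits$env_start), , drop = FALSE]
  da <- data.frame(domain = hits$domain, clan = hits$clan,
                   terminal_variant = hits$terminal_variant,
                   stringsAsFactors = FALSE)
  class(da) <- c("domain_architecture", "data.frame")
  da
}

#' Canonicalize domain tokens for comparison
#'
#' Replaces a domain by its clan when it has one, and strips N/C/M
#' terminal-variant suffixes (`_N`, `_C`, `_M`) so split variants of one
#' domain compare equal.
#'
#' @param domains Character vector of domain names.
#' @param clan_map Named character vector mapping domain -> clan (empty
#'   string or missing = no clan).
#' @return Character vector of canonical tokens.
#' @export
canonical_tokens <- function(domains, clan_map = character(0)) {
  base <- sub("_(N|C|M)$", "", domains)
  cl <- clan_map[base]
  ifelse(!is.na(cl) & nzchar(cl), cl, base)
}

#' k-shingles of a domain architecture
#'
#' Consecutive k-tuples of tokens; an architecture shorter than `k` yields
#' a single shingle holding the whole architecture.
#'
#' @param tokens Character vector of (canonical) domain tokens, in order.
#' @param k Shingle width (default 2).
#' @return Character vector of unique shingles (tuples joined by `">"`).
#' @export
shingles <- function(tokens, k = 2L) {
  stopifnot(k >= 1)
  if (length(tokens) == 0) stop("shingles: empty domain architecture")
  if (length(tokens) < k) return(paste(tokens, collapse = ">"))
  n <- length(tokens) - k + 1
  unique(vapply(seq_len(n), function(i)
    paste(tokens[i:(i + k - 1)], collapse = ">"), character(1)))
}

#' Clan-aware Jaccard similarity of two shingle sets
#'
#' Domains must be canonicalized (clan-collapsed, terminal variants
#' stripped) before shingling; this function applies [canonical_tokens()]
#' to each shingle component for safety when a `clan_map` is supplied.
#'
#' @param s1,s2 Character vectors of shingles (as from [shingles()]).
#' @param clan_map Optional domain -> clan map applied to shingle parts.
#' @return Jaccard similarity in `[0, 1]`.
#' @export
clan_jaccard <- function(s1, s2, clan_map = character(0)) {
  canon <- function(s) {
    unique(vapply(strsplit(s, ">", fixed = TRUE), function(p)
      paste(canonical_tokens(p, clan_map), collapse = ">"), character(1)))
  }
  a <- canon(s1); b <- canon(s2)
  u <- union(a, b)
  if (length(u) == 0) return(1)
  length(intersect(a, b)) / length(u)
}

#' Functional homogeneity of a cluster's domain annotations
#'
#' Median clan-aware Jaccard similarity over all pairs of annotated genes;
#' the cluster is kept only when the median equals 1. Clusters with fewer
#' than two annotated genes pass by default (unannotated genes are excluded
#' from the median).
#'
#' @param gene_das Named list of domain architectures (data frames as from
#'   [domain_architecture()]), one per annotated gene.
#' @param clan_map Domain -> clan map.
#' @param k Shingle width.
#' @return List with `median_similarity` (NA when < 2 annotated genes) and
#'   `keep` (logical).
#' @export
cluster_functional_homogeneity <- function(gene_das, clan_map = character(0),
                                           k = 2L) {
  gene_das <- Filter(function(d) nrow(d) > 0, gene_das)
  if (length(gene_das) < 2)
    return(list(median_similarity = NA_real_, keep = TRUE))
  sets <- lapply(gene_das, function(d) {
    tok <- canonical_tokens(d$domain, clan_map)
    ## adjacent repeats of one canonical token are terminal-variant splits
    ## of a single domain, not architecture
    tok <- tok[c(TRUE, tok[-1] != tok[-length(tok)])]
    shingles(tok, k)
  })
  n <- length(sets)
  sims <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    sims <- c(sims, clan_jaccard(sets[[i]], sets[[j]]))
  med <- median(sims)
  list(median_similarity = med, keep = med >= 1)
}

#' Shannon entropy of annotation labels
#'
#' Empirical entropy `H = -sum p_i ln p_i` (natural log) over the label
#' frequencies; 0 for a homogeneous set.
#'
#' @param labels Non-empty vector of annotation labels.
#' @return Entropy in nats.
#' @export
annotation_entropy <- function(labels) {
  if (length(labels) == 0) stop("annotation_entropy: empty label set")
  p <- table(labels) / length(labels)
  -sum(p * log(p))
}
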