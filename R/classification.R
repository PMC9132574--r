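## Partition of validated clusters into the four categories: consensus
## domain-architecture inference for annotated clusters (K vs GU), nested
## homolog-search voting for unannotated ones (KWP / GU / EU), the
## remote-homology refinement screens, the high-quality subset and the
## non-redundant domain-architecture set.

#' DUF predicate
#'
#' A domain is a "domain of unknown function" when its name matches
#' `^DUF[0-9]+` (terminal variants allowed) or belongs to a configured
#' accession list.
#'
#' @param domains Character vector of domain names.
#' @param duf_list Extra accessions treated as DUFs.
#' @return Logical vector.
#' @export
is_duf <- function(domains, duf_list = character(0)) {
  grepl("^DUF[0-9]+", domains) | sub("_(N|C|M)$", "", domains) %in% duf_list
}

#' Consensus domain architecture of a cluster
#'
#' Consecutive repeats of the same domain are collapsed within each gene;
#' the collapsed architectures are overlaid on a directed graph with
#' virtual source and sink, each gene adding weight 1 (complete) or 0.5
#' (incomplete) to every transition it traverses. The consensus is the
#' maximum-weight source-to-sink path; ties prefer the path supported by
#' more complete genes, then the lexicographically smallest path.
#'
#' @param gene_das Named list of character vectors: each gene's ordered
#'   domain names (at least one annotated gene).
#' @param complete Named logical vector: gene completeness (names covering
#'   `gene_das`; missing names count as incomplete).
#' @return Character vector: the consensus ordered domain list.
#' @export
consensus_da <- function(gene_das, complete = logical(0)) {
  gene_das <- Filter(length, gene_das)
  if (length(gene_das) == 0) stop("consensus_da: no annotated genes")
  collapse <- function(x) x[c(TRUE, x[-1] != x[-length(x)])]
  gene_das <- lapply(gene_das, collapse)
  if (length(gene_das) == 1) return(gene_das[[1]])
  w <- new.env(parent = emptyenv())
  wc <- new.env(parent = emptyenv())
  add <- function(env, key, v) assign(key, v + (if (!is.null(env[[key]])) env[[key]] else 0), envir = env)
  for (g in names(gene_das)) {
    path <- c(".SRC", gene_das[[g]], ".SNK")
    wt <- if (isTRUE(complete[g])) 1 else 0.5
    for (i in seq_len(length(path) - 1)) {
      key <- paste(path[i], path[i + 1], sep = "\r")
      add(w, key, wt)
      add(wc, key, if (isTRUE(complete[g])) 1 else 0)
    }
  }
  keys <- ls(w, all.names = TRUE)
  parts <- strsplit(keys, "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(parts, `[`, "", 1),
                      to = vapply(parts, `[`, "", 2),
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = TRUE)
  paths <- igraph::all_simple_paths(g, ".SRC", ".SNK", mode = "out")
  score <- function(p, env) {
    nm <- names(p)
    sum(vapply(seq_len(length(nm) - 1), function(i)
      env[[paste(nm[i], nm[i + 1], sep = "\r")]], numeric(1)))
  }
  tw <- vapply(paths, score, numeric(1), env = w)
  best <- which(tw >= max(tw) - 1e-9)
  if (length(best) > 1) {
    tc <- vapply(paths[best], score, numeric(1), env = wc)
    best <- best[tc >= max(tc) - 1e-9]
  }
  if (length(best) > 1) {
    strs <- vapply(paths[best], function(p)
      paste(names(p), collapse = ">"), character(1))
    best <- best[order(strs)[1]]
  }
  nm <- names(paths[[best[1]]])
  nm[!nm %in% c(".SRC", ".SNK")]
}

#' Classify a Pfam-annotated cluster as Known or Genomic Unknown
#'
#' Genomic Unknown when every consensus domain is a DUF; Known as soon as
#' one domain has known function.
#'
#' @param consensus Character vector of consensus domains (non-empty).
#' @param duf_list Extra DUF accessions.
#' @return `"K"` or `"GU"`.
#' @export
classify_annotated <- function(consensus, duf_list = character(0)) {
  if (length(consensus) == 0) stop("classify_annotated: empty consensus")
  if (all(is_duf(consensus, duf_list))) "GU" else "K"
}

#' Keep the confident homolog group around the best hit
#'
#' With `L = |log10(best e-value)|`, retains hits whose `|log10 e-value|`
#' is at least `factor * L` (i.e. within 60 percent of the log of the best
#' e-value by default). The best hit is always retained.
#'
#' @param hits Homolog-hit data frame with an `evalue` column.
#' @param factor Log-space retention factor (default 0.6).
#' @return The retained subset.
#' @export
filter_homologs <- function(hits, factor = 0.6) {
  stopifnot(nrow(hits) >= 1)
  lg <- abs(log10(hits$evalue))
  keep <- lg >= factor * max(lg)
  keep[which.max(lg)] <- TRUE
  hits[keep, , drop = FALSE]
}

#' Quorum-majority vote over homolog annotations
#'
#' A hit counts as "unknown" when its target annotation matches any of the
#' unknown-function terms (case-insensitive substring) or its target is a
#' DUF. The verdict is `"unknown"` only with a strict majority; ties go to
#' `"known"` (unknown status requires positive evidence).
#'
#' @param hits Homolog-hit data frame (`target_annotation`,
#'   `target_is_duf`).
#' @param unknown_terms Term list, see [default_unknown_terms()].
#' @param weight_by_bitscore If TRUE, votes are weighted by `bitscore`.
#' @return `"known"` or `"unknown"`.
#' @export
vote_category <- function(hits, unknown_terms = default_unknown_terms(),
                          weight_by_bitscore = FALSE) {
  stopifnot(nrow(hits) >= 1)
  ann <- tolower(hits$target_annotation)
  unk <- Reduce(`|`, lapply(tolower(unknown_terms), function(t)
    grepl(t, ann, fixed = TRUE)), rep(FALSE, nrow(hits)))
  if (!is.null(hits$target_is_duf)) unk <- unk | isTRUE_vec(hits$target_is_duf)
  wts <- if (weight_by_bitscore) hits$bitscore else rep(1, nrow(hits))
  if (sum(wts[unk]) > 0.5 * sum(wts)) "unknown" else "known"
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Classify an unannotated cluster from its nested homolog searches
#'
#' Stage 1: hits against the general protein reference (UniRef90-like) are
#' filtered ([filter_homologs()]) and voted; unknown -> GU, known -> KWP.
#' Stage 2: with no stage-1 hits, the same on the broader reference
#' (nr-like). Stage 3: no hits anywhere -> EU.
#'
#' @param uniref_hits,nr_hits Homolog-hit data frames (0 rows = no hits).
#' @param unknown_terms Term list.
#' @param factor Retention factor for [filter_homologs()].
#' @return List with `category` in `{"KWP","GU","EU"}` and `evidence`.
#' @export
classify_unannotated <- function(uniref_hits, nr_hits,
                                 unknown_terms = default_unknown_terms(),
                                 factor = 0.6) {
  stage <- function(hits, label) {
    kept <- filter_homologs(hits, factor)
    v <- vote_category(kept, unknown_terms)
    list(category = if (v == "unknown") "GU" else "KWP",
         evidence = sprintf("vote(%s,n=%d,%s)", label, nrow(kept), v))
  }
  if (nrow(uniref_hits) > 0) return(stage(uniref_hits, "uniref"))
  if (nrow(nr_hits) > 0) return(stage(nr_hits, "nr"))
  list(category = "EU", evidence = "no_hits")
}

#' Refine an Environmental Unknown cluster by profile homology
#'
#' Profile hits with probability >= `min_prob` re-open the vote: a known
#' majority moves the cluster to KWP, an unknown majority to GU; with no
#' qualifying hits it stays EU.
#'
#' @param hits Data frame with `probability`, `target_annotation`,
#'   `target_is_duf` (0 rows allowed).
#' @param unknown_terms Term list.
#' @param min_prob Probability threshold (default 0.90).
#' @return `"EU"`, `"GU"` or `"KWP"`.
#' @export
refine_eu <- function(hits, unknown_terms = default_unknown_terms(),
                      min_prob = 0.90) {
  q <- hits[!is.na(hits$probability) & hits$probability >= min_prob, ,
            drop = FALSE]
  if (nrow(q) == 0) return("EU")
  if (vote_category(q, unknown_terms) == "unknown") "GU" else "KWP"
}

#' Refine a Known-without-Pfam cluster against Pfam profiles
#'
#' Hits qualifying with probability >= `min_prob` and target coverage >
#' `min_cov` route the cluster: any hit to a known-function Pfam domain ->
#' K; qualifying hits to DUFs only -> GU; no qualifying hits -> KWP. When
#' the table carries query coordinates (`qstart`, `qend`) and `evalue`,
#' hits overlapping by more than half of the shorter envelope are resolved
#' keeping the smaller e-value before routing.
#'
#' @param hits Data frame with `probability`, `target_cov`, `target`
#'   (domain name); optional `qstart`, `qend`, `evalue`.
#' @param duf_list Extra DUF accessions.
#' @param min_prob Probability threshold (default 0.90).
#' @param min_cov Target-coverage threshold (default 0.60).
#' @return `"KWP"`, `"GU"` or `"K"`.
#' @export
refine_kwp <- function(hits, duf_list = character(0), min_prob = 0.90,
                       min_cov = 0.60) {
  q <- hits[!is.na(hits$probability) & hits$probability >= min_prob &
              hits$target_cov > min_cov, , drop = FALSE]
  if (nrow(q) == 0) return("KWP")
  if (all(c("qstart", "qend", "evalue") %in% names(q)) && nrow(q) > 1) {
    q <- q[order(q$evalue), , drop = FALSE]
    keep <- rep(TRUE, nrow(q))
    for (i in 2:nrow(q)) for (j in seq_len(i - 1)) {
      if (!keep[j]) next
      ov <- min(q$qend[i], q$qend[j]) - max(q$qstart[i], q$qstart[j]) + 1
      shorter <- min(q$qend[i] - q$qstart[i], q$qend[j] - q$qstart[j]) + 1
      if (ov > 0.5 * shorter) { keep[i] <- FALSE; break }
    }
    q <- q[keep, , drop = FALSE]
  }
  if (any(!is_duf(q$target, duf_list))) "K" else "GU"
}

#' Flag the high-quality cluster subset
#'
#' A cluster is high-quality when its representative is a complete gene and
#' its fraction of complete genes exceeds both 1/3 and the broken-stick
#' threshold over the completeness-fraction distribution of all clusters.
#'
#' @param clusters A `gc_clusters` object.
#' @param genes A `gc_genes` data frame.
#' @return The clusters with `is_high_quality` set; the threshold used is
#'   attached as attribute `"hq_threshold"`.
#' @export
select_high_quality <- function(clusters, genes) {
  comp <- setNames(genes$is_complete, genes$id)
  frac <- vapply(clusters$members, function(m) mean(isTRUE_vec(comp[m])),
                 numeric(1))
  bs <- if (length(frac) < 2 || all(frac == 0)) 0
        else broken_stick_threshold(frac)
  thr <- max(1 / 3, bs)
  rep_complete <- isTRUE_vec(comp[clusters$representative])
  clusters$is_high_quality <- rep_complete & frac > thr
  attr(clusters, "hq_threshold") <- thr
  clusters
}

.qgram_profile <- function(s, q = 3L) {
  if (nchar(s) < q) return(table(s))
  grams <- substring(s, seq_len(nchar(s) - q + 1), q:nchar(s))
  table(grams)
}

#' q-gram cosine distance between two strings
#'
#' @param a,b Strings.
#' @param q Gram size (default 3).
#' @return Distance in `[0, 1]` (0 = identical profiles).
#' @export
qgram_cosine_distance <- function(a, b, q = 3L) {
  pa <- .qgram_profile(a, q); pb <- .qgram_profile(b, q)
  keys <- union(names(pa), names(pb))
  va <- as.numeric(pa[keys]); va[is.na(va)] <- 0
  vb <- as.numeric(pb[keys]); vb[is.na(vb)] <- 0
  1 - sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

#' Collapse fragmented domain architectures into a non-redundant set
#'
#' Candidate pairs are architectures within 3-gram cosine distance < 0.9 of
#' each other (on the token string). A fragmented architecture that is a
#' contiguous sub-architecture of a larger one, and whose cluster has fewer
#' than `min_complete` complete genes, is collapsed into the larger one.
#'
#' @param das List of character vectors (ordered domain tokens).
#' @param complete_frac Numeric vector, fraction of complete genes backing
#'   each architecture.
#' @param max_dist Cosine-distance cutoff for candidate pairs (default 0.9).
#' @param min_complete Complete-gene fraction below which a fragment is
#'   collapsed (default 0.75).
#' @return List with `assignment` (index of the surviving architecture each
#'   input maps to) and `das` (the distinct surviving architectures).
#' @export
collapse_fragmented_das <- function(das, complete_frac, max_dist = 0.9,
                                    min_complete = 0.75) {
  stopifnot(length(das) == length(complete_frac))
  n <- length(das)
  strs <- vapply(das, paste, "", collapse = "|")
  assign_to <- seq_len(n)
  is_subarch <- function(f, l) {
    nf <- length(f); nl <- length(l)
    if (nf >= nl) return(FALSE)
    any(vapply(seq_len(nl - nf + 1), function(i)
      all(l[i:(i + nf - 1)] == f), logical(1)))
  }
  for (i in seq_len(n)) {
    if (complete_frac[i] >= min_complete) next
    cands <- which(lengths(das) > length(das[[i]]))
    best <- NA_integer_
    for (j in cands) {
      if (qgram_cosine_distance(strs[i], strs[j]) >= max_dist) next
      if (!is_subarch(das[[i]], das[[j]])) next
      if (is.na(best) || length(das[[j]]) > length(das[[best]])) best <- j
    }
    if (!is.na(best)) assign_to[i] <- best
  }
  ## follow chains (fragment of a fragment), then dedupe identical strings
  repeat {
    nxt <- assign_to[assign_to]
    if (identical(nxt, assign_to)) break
    assign_to <- nxt
  }
  surv_str <- strs[sort(unique(assign_to))]
  canon <- match(strs[assign_to], unique(surv_str))
  list(assignment = canon,
       das = lapply(unique(surv_str), function(s)
         strsplit(s, "|", fixed = TRUE)[[1]]))
}

#' Classify validated clusters into K / KWP / GU / EU
#'
#' Clusters with at least one Pfam-annotated gene go through consensus
#' domain-architecture inference and the K/GU split; unannotated clusters
#' go through the nested homolog-search vote (KWP/GU/EU). Optional
#' refinement tables re-route EUs and KWPs by remote profile homology.
#'
#' @param clusters A validated `gc_clusters` object (flagged and DISCARDED
#'   clusters are skipped).
#' @param domain_hits Domain-hit data frame (canonical columns).
#' @param uniref_hits,nr_hits Homolog-hit data frames with cluster ids in
#'   `query`.
#' @param genes `gc_genes` data frame (for completeness weighting).
#' @param eu_profile_hits,kwp_profile_hits Optional refinement tables with
#'   cluster ids in column `query`; see [refine_eu()], [refine_kwp()].
#' @param unknown_terms,duf_list Configuration of the unknown vocabulary.
#' @return List with `clusters` (categories filled in), `decisions` (one
#'   row per cluster: category, evidence) and `consensus_das` (named list
#'   for annotated clusters).
#' @export
classify_clusters <- function(clusters, domain_hits, uniref_hits, nr_hits,
                              genes,
                              eu_profile_hits = NULL,
                              kwp_profile_hits = NULL,
                              unknown_terms = default_unknown_terms(),
                              duf_list = character(0)) {
  comp <- setNames(genes$is_complete, genes$id)
  dh_by_gene <- split(domain_hits, domain_hits$gene_id)
  ur_by_gc <- split(uniref_hits, uniref_hits$query)
  nr_by_gc <- split(nr_hits, nr_hits$query)
  eu_by_gc <- if (!is.null(eu_profile_hits))
    split(eu_profile_hits, eu_profile_hits$query) else list()
  kwp_by_gc <- if (!is.null(kwp_profile_hits))
    split(kwp_profile_hits, kwp_profile_hits$query) else list()
  todo <- which(!clusters$flagged &
                  (is.na(clusters$category) | clusters$category != "DISCARDED"))
  cons <- list()
  dec <- vector("list", length(todo))
  empty_h <- data.frame()[0, ]
  for (k in seq_along(todo)) {
    i <- todo[k]
    id <- clusters$id[i]
    mem <- clusters$members[[i]]
    gd <- dh_by_gene[intersect(mem, names(dh_by_gene))]
    if (length(gd) > 0) {
      gene_das <- lapply(gd, function(h)
        h$domain[order(h$env_start)])
      da <- consensus_da(gene_das, comp)
      cat0 <- classify_annotated(da, duf_list)
      ev <- "consensus_da"
      cons[[id]] <- da
    } else {
      res <- classify_unannotated(
        if (!is.null(ur_by_gc[[id]])) ur_by_gc[[id]] else uniref_hits[0, ],
        if (!is.null(nr_by_gc[[id]])) nr_by_gc[[id]] else nr_hits[0, ],
        unknown_terms)
      cat0 <- res$category
      ev <- res$evidence
    }
    if (cat0 == "EU" && !is.null(eu_by_gc[[id]])) {
      new <- refine_eu(eu_by_gc[[id]], unknown_terms)
      if (new != "EU") ev <- paste0(ev, ";refined_from:EU")
      cat0 <- new
    }
    if (cat0 == "KWP" && !is.null(kwp_by_gc[[id]])) {
      new <- refine_kwp(kwp_by_gc[[id]], duf_list)
      if (new != "KWP") ev <- paste0(ev, ";refined_from:KWP")
      cat0 <- new
    }
    clusters$category[i] <- cat0
    dec[[k]] <- data.frame(cluster_id = id, category = cat0, evidence = ev,
                           stringsAsFactors = FALSE)
  }
  list(clusters = clusters,
       decisions = do.call(rbind, dec),
       consensus_das = cons)
}
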