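## The gene-cluster container: a data frame with one row per cluster and a
## list-column of member gene ids, in the spirit of how limma/edgeR keep
## per-feature metadata alongside the core object.

#' Build a gene-cluster set from representative/member pairs
#'
#' @param pairs Data frame with columns `representative` and `member`
#'   (one row per member; the representative is expected to appear as its
#'   own member).
#' @return A `gc_clusters` data frame with columns `id`, `representative`,
#'   `category` (NA until classified), `flagged`, `is_high_quality` and a
#'   list-column `members`.
#' @export
gene_clusters <- function(pairs) {
  stopifnot(all(c("representative", "member") %in% names(pairs)))
  dup <- !duplicated(pairs$member)
  two_reps <- tapply(pairs$representative, pairs$member,
                     function(x) length(unique(x)))
  if (any(two_reps > 1))
    stop("member mapped to two representatives: ",
         names(two_reps)[two_reps > 1][1])
  members <- split(pairs$member, pairs$representative)
  reps <- names(members)
  members <- lapply(seq_along(members), function(i)
    unique(c(reps[i], members[[i]])))
  cl <- data.frame(id = reps, representative = reps,
                   category = NA_character_, flagged = FALSE,
                   is_high_quality = FALSE, stringsAsFactors = FALSE)
  cl$members <- members
  class(cl) <- c("gc_clusters", "data.frame")
  rownames(cl) <- NULL
  cl
}

#' @export
print.gc_clusters <- function(x, ...) {
  cat("gc_clusters: ", nrow(x), " clusters, ",
      sum(lengths(x$members)), " genes\n", sep = "")
  if (!all(is.na(x$category))) {
    tab <- table(x$category, useNA = "ifany")
    cat("categories: ", paste(names(tab), tab, sep = "=", collapse = " "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Cluster sizes
#' @param clusters A `gc_clusters` object.
#' @return Integer vector named by cluster id.
#' @export
cluster_sizes <- function(clusters) {
  setNames(lengths(clusters$members), clusters$id)
}
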