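## End-to-end orchestration: validation -> functional screen ->
## classification -> communities -> ecology -> phylogenomics, with a
## summary whose category partition is exhaustive and mutually exclusive.

#' Run the full pipeline on a synthetic (or assembled) input bundle
#'
#' @param sim A bundle as returned by [simulate_dataset()], or a list with
#'   the same components assembled from files.
#' @param min_cluster_size Size below which clusters are flagged (default
#'   10).
#' @param grid Inflation grid for the Known community scan.
#' @param n_datasets,n_null Niche-breadth vote parameters.
#' @param seed Seed for the stochastic stages (ecology).
#' @param verbose Print stage progress.
#' @return List with per-stage results and a `summary` list.
#' @export
run_pipeline <- function(sim, min_cluster_size = 10L,
                         grid = seq(1.2, 3.0, by = 0.1),
                         n_datasets = 10L, n_null = 100L, seed = 1L,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  ev <- sim$evidence
  ## 1. validation
  say("validating clusters ...")
  cl <- flag_small_clusters(sim$clusters, min_cluster_size)
  val <- validate_clusters(cl, sim$genes)
  cl <- val$clusters
  ## 2. functional homogeneity screen
  say("functional homogeneity ...")
  dh_by_gene <- split(ev$domain_hits, ev$domain_hits$gene_id)
  keep_fun <- vapply(seq_len(nrow(cl)), function(i) {
    if (cl$flagged[i] || identical(cl$category[i], "DISCARDED")) return(TRUE)
    das <- lapply(intersect(cl$members[[i]], names(dh_by_gene)), function(g)
      domain_architecture(dh_by_gene[[g]]))
    cluster_functional_homogeneity(das, ev$clan_map)$keep
  }, logical(1))
  cl$category[!keep_fun] <- "DISCARDED"
  ## 3. classification + refinement + HQ subset
  say("classifying clusters ...")
  cls <- classify_clusters(cl, ev$domain_hits, ev$uniref_hits, ev$nr_hits,
                           sim$genes)
  cl <- select_high_quality(cls$clusters, sim$genes)
  ## non-redundant architecture set (Known clusters)
  k_ids <- cl$id[!is.na(cl$category) & cl$category == "K"]
  k_das <- cls$consensus_das[intersect(k_ids, names(cls$consensus_das))]
  comp <- setNames(sim$genes$is_complete, sim$genes$id)
  nr_das <- if (length(k_das)) {
    cf <- vapply(names(k_das), function(id)
      mean(isTRUE_vec(comp[cl$members[[match(id, cl$id)]]])), numeric(1))
    collapse_fragmented_das(unname(k_das), cf)
  } else NULL
  ## 4. communities
  say("inferring communities ...")
  cat_ids <- split(cl$id, cl$category)[GC_CATEGORIES]
  names(cat_ids) <- GC_CATEGORIES
  cat_ids <- Filter(Negate(is.null), cat_ids)
  comm <- infer_communities(cat_ids, ev$profile_hits,
                            consensus_das = cls$consensus_das,
                            clan_map = ev$clan_map,
                            n_das = if (!is.null(nr_das))
                              length(nr_das$das) else NULL,
                            grid = grid)
  ## 5. ecology
  say("ecology ...")
  glen <- setNames(nchar(sim$genes$sequence), sim$genes$id)
  abundance <- cluster_abundance(sim$ecology$coverage, glen, cl)
  retained <- select_samples(sim$ecology$gene_counts)
  calls <- distribution_calls(abundance[, retained, drop = FALSE],
                              n_datasets = n_datasets, n_null = n_null,
                              seed = seed)
  accum <- accumulation_curve(abundance, n_perm = 100L, seed = seed)
  ## 6. phylogenomics
  say("phylogenomics ...")
  pres <- sim$phylo$presence
  lin <- lapply(pres, function(p) lineage_f1(sim$phylo$tree, p))
  tau <- vapply(pres, function(p)
    as.numeric(consentrait_tau(sim$phylo$tree, p)), numeric(1))
  ## summary
  validated <- !cl$flagged &
    (is.na(cl$category) | cl$category != "DISCARDED")
  cat_tab <- table(factor(cl$category[validated], GC_CATEGORIES))
  summary <- list(
    n_clusters = nrow(cl),
    n_flagged = sum(cl$flagged),
    n_discarded = sum(!is.na(cl$category) & cl$category == "DISCARDED"),
    categories = as.list(cat_tab),
    n_high_quality = sum(cl$is_high_quality),
    n_communities = vapply(comm[intersect(GC_CATEGORIES, names(comm))],
                           function(x) length(unique(x$partition)),
                           numeric(1)),
    inflation = if (!is.null(comm$K$inflation)) comm$K$inflation else NA,
    distribution = as.list(table(calls$call)),
    n_lineage_specific = sum(vapply(lin, `[[`, logical(1),
                                    "is_lineage_specific")),
    unknown_known_abundance_ratio = .unknown_ratio(abundance, cl)
  )
  list(clusters = cl, validation = val, classification = cls,
       nr_das = nr_das, communities = comm, abundance = abundance,
       distribution = calls, accumulation = accum,
       lineage = lin, tau = tau, summary = summary)
}

## per-sample ratio of unknown (GU+EU) to known (K+KWP) summed abundance
.unknown_ratio <- function(abundance, clusters) {
  cat <- clusters$category[match(rownames(abundance), clusters$id)]
  unk <- colSums(abundance[cat %in% c("GU", "EU"), , drop = FALSE])
  kn <- colSums(abundance[cat %in% c("K", "KWP"), , drop = FALSE])
  ifelse(kn > 0, unk / kn, NA_real_)
}

#' Write a simulated bundle to a directory of plain-text inputs
#'
#' Emits the FASTA, membership TSV, evidence TSVs, coverage TSV, Newick
#' tree, presence TSV and the truth JSON, i.e. the full on-disk interface
#' of the CLI.
#'
#' @param sim A bundle from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_genes(sim$genes, fp("genes.fasta"))
  write_cluster_membership(sim$clusters, fp("membership.tsv"))
  write_hits(sim$evidence$domain_hits, fp("domains.tsv"))
  write_hits(sim$evidence$uniref_hits, fp("uniref_hits.tsv"))
  write_hits(sim$evidence$nr_hits, fp("nr_hits.tsv"))
  for (cat in names(sim$evidence$profile_hits))
    write_hits(sim$evidence$profile_hits[[cat]],
               fp(sprintf("profile_hits_%s.tsv", cat)))
  data.table::fwrite(sim$ecology$coverage, fp("coverage.tsv"), sep = "\t")
  data.table::fwrite(data.table::data.table(
    sample = names(sim$ecology$gene_counts),
    gene_count = as.integer(sim$ecology$gene_counts)),
    fp("gene_counts.tsv"), sep = "\t")
  ape::write.tree(sim$phylo$tree, fp("genome_tree.nwk"))
  pres <- sim$phylo$presence
  data.table::fwrite(data.table::data.table(
    gc_id = rep(names(pres), lengths(pres)), genome = unlist(pres)),
    fp("presence.tsv"), sep = "\t")
  jsonlite::write_json(list(families = sim$truth$families,
                            genes = sim$truth$genes),
                       fp("truth.json"), dataframe = "columns")
  invisible(dir)
}
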