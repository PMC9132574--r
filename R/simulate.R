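## Seeded synthetic-data generator: every input the pipeline consumes,
## with planted ground truth (family membership, category, community,
## distribution class, lineage clade, intruder genes). The amino-acid
## alphabet is uniform over the 20 residues; mutations are iid
## substitutions with no indels, which keeps the naive padding aligner
## valid for the fixtures.

.AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.random_protein <- function(len) paste(sample(.AA, len, TRUE), collapse = "")

.mutate <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- runif(length(ch)) < rate
  ch[hit] <- sample(.AA, sum(hit), TRUE)
  paste(ch, collapse = "")
}

#' Simulate gene families with planted intruders
#'
#' Each family is a random root protein (length 80-400) plus point-mutated
#' copies; intruders are unrelated random sequences inserted into clusters
#' at `intruder_rate` per member slot. Completeness flags are assigned at
#' `complete_frac`. Fully deterministic given the seed.
#'
#' @param n_families,genes_per_family Family count and size.
#' @param mutation_rate Per-site substitution probability of members
#'   against the family root (default 0.1).
#' @param intruder_rate Expected intruders per member slot (default 0).
#' @param complete_frac Fraction of complete genes (default 0.7).
#' @param seed Random seed.
#' @return List: `genes` (`gc_genes`), `clusters` (`gc_clusters`), `truth`
#'   (`$genes`: gene_id, family, is_intruder; `$families`: family,
#'   cluster_id).
#' @export
simulate_families <- function(n_families = 200L, genes_per_family = 20L,
                              mutation_rate = 0.1, intruder_rate = 0,
                              complete_frac = 0.7, seed = 1L) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            intruder_rate >= 0, intruder_rate <= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fam_ids <- sprintf("F%04d", seq_len(n_families))
  rows <- vector("list", n_families)
  truth <- vector("list", n_families)
  for (i in seq_len(n_families)) {
    root <- .random_protein(sample(80:400, 1))
    ids <- sprintf("%s_g%02d", fam_ids[i], seq_len(genes_per_family))
    seqs <- vapply(seq_len(genes_per_family), function(k)
      .mutate(root, mutation_rate), character(1))
    n_int <- rbinom(1, genes_per_family, intruder_rate)
    if (n_int > 0) {
      iid <- sprintf("%s_i%02d", fam_ids[i], seq_len(n_int))
      ids <- c(ids, iid)
      seqs <- c(seqs, vapply(seq_len(n_int), function(k)
        .random_protein(sample(80:400, 1)), character(1)))
    }
    rows[[i]] <- data.frame(
      id = ids, sequence = seqs,
      is_complete = runif(length(ids)) < complete_frac,
      origin = "sim", contig = ids, start = 1L,
      end = nchar(seqs) * 3L, strand = "+", flags = "",
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      gene_id = ids, family = fam_ids[i],
      is_intruder = grepl("_i", ids, fixed = TRUE),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  class(genes) <- c("gc_genes", "data.frame")
  truth_genes <- do.call(rbind, truth)
  pairs <- data.frame(representative = truth_genes$family,
                      member = truth_genes$gene_id,
                      stringsAsFactors = FALSE)
  pairs$representative <- paste0(pairs$representative, "_g01")
  clusters <- gene_clusters(pairs)
  fam_tab <- data.frame(family = fam_ids,
                        cluster_id = paste0(fam_ids, "_g01"),
                        stringsAsFactors = FALSE)
  list(genes = genes, clusters = clusters,
       truth = list(genes = truth_genes, families = fam_tab))
}

.known_annotations <- c(
  "ABC transporter ATP-binding protein", "DNA polymerase III subunit",
  "serine/threonine protein kinase", "ribosomal protein L2",
  "glycosyltransferase family 2", "two-component sensor histidine kinase",
  "aminotransferase class I", "efflux RND transporter permease")
.unknown_annotations <- c(
  "hypothetical protein", "uncharacterized protein",
  "protein of unknown function", "predicted protein")

#' Simulate annotation and homology evidence with planted categories
#'
#' Families receive a planted category (K, KWP, GU, EU) and a planted
#' community. K families get known-domain annotations shared within the
#' community; GU families get either DUF-only annotations or
#' unknown-function homologs; KWP families get functional homologs (some
#' only in the second-tier table); EU families get no hits. Families in
#' one planted community emit mutual profile hits passing the community
#' edge thresholds. `noise` corrupts each evidence row independently.
#'
#' @param sim Output of [simulate_families()].
#' @param noise Per-row corruption probability in `[0, 1]`.
#' @param seed Random seed.
#' @param category_probs Sampling weights for K/KWP/GU/EU (default
#'   0.4/0.2/0.25/0.15).
#' @param community_sizes Candidate planted community sizes (default 1:4).
#' @return List: `domain_hits`, `uniref_hits`, `nr_hits`, `profile_hits`
#'   (list per category), `clan_map`, and updated `truth` (`$families`
#'   gains `category`, `community`, `da`).
#' @export
simulate_evidence <- function(sim, noise = 0, seed = 1L,
                              category_probs = c(K = 0.4, KWP = 0.2,
                                                 GU = 0.25, EU = 0.15),
                              community_sizes = 1:4) {
  stopifnot(noise >= 0, noise <= 1)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fams <- sim$truth$families
  n <- nrow(fams)
  fams$category <- sample(names(category_probs), n, TRUE,
                          prob = category_probs)
  ## planted communities: contiguous blocks within each category
  fams$community <- NA_character_
  for (cat in unique(fams$category)) {
    idx <- which(fams$category == cat)
    com <- 0L; pos <- 1L
    while (pos <= length(idx)) {
      com <- com + 1L
      sz <- sample(community_sizes, 1)
      take <- idx[pos:min(pos + sz - 1, length(idx))]
      fams$community[take] <- sprintf("%s_c%03d", cat, com)
      pos <- pos + sz
    }
  }
  ## domain vocabulary: known Pfam-like domains with clans, and DUFs
  known_pool <- sprintf("PF%05d", 1:60)
  clan_map <- setNames(sprintf("CL%04d", rep(1:30, each = 2)), known_pool)
  duf_pool <- sprintf("DUF%d", 1000:1059)
  ## one architecture per community (annotated categories)
  fams$da <- NA_character_
  for (com in unique(fams$community)) {
    rows <- which(fams$community == com)
    cat <- fams$category[rows[1]]
    if (cat == "K") {
      len <- sample(1:3, 1)
      fams$da[rows] <- paste(sample(known_pool, len), collapse = "|")
    } else if (cat == "GU") {
      len <- sample(1:2, 1)
      fams$da[rows] <- paste(sample(duf_pool, len), collapse = "|")
    }
  }
  ## half the GU families rely on unknown-term homologs instead of DUFs
  gu <- which(fams$category == "GU")
  gu_homolog <- gu[seq_along(gu) %% 2 == 0]
  fams$da[gu_homolog] <- NA_character_
  genes_by_fam <- split(sim$truth$genes$gene_id[!sim$truth$genes$is_intruder],
                        sim$truth$genes$family[!sim$truth$genes$is_intruder])
  corrupt <- function(n) runif(n) < noise
  ## --- domain hits ---
  dh <- list()
  for (i in which(!is.na(fams$da))) {
    doms <- strsplit(fams$da[i], "|", fixed = TRUE)[[1]]
    for (g in genes_by_fam[[fams$family[i]]]) {
      dom_out <- doms
      flip <- corrupt(length(doms))
      if (any(flip)) {
        swap <- ifelse(grepl("^DUF", dom_out[flip]),
                       sample(known_pool, sum(flip), TRUE),
                       sample(duf_pool, sum(flip), TRUE))
        dom_out[flip] <- swap
      }
      k <- length(dom_out)
      starts <- cumsum(c(1, rep(60, k - 1)))
      dh[[length(dh) + 1]] <- data.frame(
        gene_id = g, domain = dom_out,
        clan = ifelse(dom_out %in% names(clan_map), clan_map[dom_out], ""),
        env_start = starts, env_end = starts + 49L,
        i_evalue = 10^-runif(k, 10, 30), coverage = runif(k, 0.6, 0.95),
        terminal_variant = "none", stringsAsFactors = FALSE)
    }
  }
  domain_hits <- if (length(dh)) do.call(rbind, dh) else
    data.frame(gene_id = character(0), domain = character(0),
               clan = character(0), env_start = integer(0),
               env_end = integer(0), i_evalue = numeric(0),
               coverage = numeric(0), terminal_variant = character(0))
  ## --- homolog hits (two nested tiers) ---
  mk_hits <- function(gc, anns) {
    k <- length(anns)
    flip <- corrupt(k)
    anns[flip] <- ifelse(anns[flip] %in% .unknown_annotations,
                         sample(.known_annotations, sum(flip), TRUE),
                         sample(.unknown_annotations, sum(flip), TRUE))
    data.frame(query = gc, target = sprintf("%s_t%02d", gc, seq_len(k)),
               evalue = 10^-runif(k, 8, 40), bitscore = runif(k, 80, 400),
               query_cov = runif(k, 0.6, 0.95),
               target_cov = runif(k, 0.6, 0.95),
               target_annotation = anns,
               target_is_duf = FALSE, stringsAsFactors = FALSE)
  }
  ur <- list(); nr <- list()
  kwp <- which(fams$category == "KWP")
  kwp_nr_only <- kwp[seq_along(kwp) %% 3 == 0]
  gu_nr_only <- gu_homolog[seq_along(gu_homolog) %% 3 == 0]
  for (i in kwp) {
    anns <- sample(.known_annotations, sample(4:8, 1), TRUE)
    tab <- mk_hits(fams$cluster_id[i], anns)
    if (i %in% kwp_nr_only) nr[[length(nr) + 1]] <- tab
    else ur[[length(ur) + 1]] <- tab
  }
  for (i in gu_homolog) {
    anns <- sample(.unknown_annotations, sample(4:8, 1), TRUE)
    tab <- mk_hits(fams$cluster_id[i], anns)
    if (i %in% gu_nr_only) nr[[length(nr) + 1]] <- tab
    else ur[[length(ur) + 1]] <- tab
  }
  empty_h <- mk_hits("x", "y")[0, ]
  uniref_hits <- if (length(ur)) do.call(rbind, ur) else empty_h
  nr_hits <- if (length(nr)) do.call(rbind, nr) else empty_h
  ## --- profile hits within planted communities, per category ---
  profile_hits <- list()
  for (cat in c("K", "KWP", "GU", "EU")) {
    ph <- list()
    for (com in unique(fams$community[fams$category == cat])) {
      members <- fams$cluster_id[fams$community == com]
      if (length(members) < 2) next
      prs <- t(combn(members, 2))
      keep <- !corrupt(nrow(prs))
      prs <- prs[keep, , drop = FALSE]
      if (!nrow(prs)) next
      cols <- sample(100:300, nrow(prs), TRUE)
      ph[[length(ph) + 1]] <- data.frame(
        query_gc = prs[, 1], target_gc = prs[, 2],
        probability = runif(nrow(prs), 0.7, 0.99),
        score = runif(nrow(prs), 1.5, 2.5) * cols,
        aligned_cols = cols,
        query_cov = runif(nrow(prs), 0.65, 0.95),
        target_cov = runif(nrow(prs), 0.65, 0.95),
        stringsAsFactors = FALSE)
    }
    profile_hits[[cat]] <- if (length(ph)) do.call(rbind, ph) else
      .empty_profile_hits()
  }
  sim$truth$families <- fams
  list(domain_hits = domain_hits, uniref_hits = uniref_hits,
       nr_hits = nr_hits, profile_hits = profile_hits,
       clan_map = clan_map, truth = sim$truth)
}

#' Simulate abundance/coverage data with planted distribution classes
#'
#' Samples are split into groups. Narrow clusters place all their mass in
#' one home group (Dirichlet profile within the group, zero elsewhere);
#' broad clusters are exactly evenly spread over all samples. Every sample
#' devotes the fraction `narrow_share` of its composition to the narrow
#' clusters homed in its group, the rest to the broad pool, so the
#' per-sample TSS profiles are exactly reproducible from the truth.
#' Per-gene coverages are consistent with the cluster abundances.
#'
#' @param sim Output of [simulate_families()] (evidence truth optional).
#' @param n_samples,n_groups Sample layout (defaults 20 and 4).
#' @param narrow_share Fraction of each sample held by narrow clusters
#'   (default 0.3).
#' @param seed Random seed.
#' @return List: `coverage` (gene_id, sample, coverage), `gene_counts`
#'   (named vector per sample), `groups` (named group id per sample), and
#'   updated `truth` (`$families` gains `distribution`, `home_group`).
#' @export
simulate_ecology <- function(sim, n_samples = 20L, n_groups = 4L,
                             narrow_share = 0.3, seed = 1L) {
  stopifnot(n_samples >= 4, n_groups >= 2, n_samples >= n_groups)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  fams <- sim$truth$families
  n <- nrow(fams)
  samples <- sprintf("S%03d", seq_len(n_samples))
  groups <- setNames(rep(seq_len(n_groups), length.out = n_samples), samples)
  fams$distribution <- rep(c("narrow", "broad"), length.out = n)
  ## round-robin home groups so every group hosts some narrow clusters and
  ## the broad pool share is identical in every sample
  fams$home_group <- NA_integer_
  narrow_idx <- which(fams$distribution == "narrow")
  fams$home_group[narrow_idx] <- rep(seq_len(n_groups),
                                     length.out = length(narrow_idx))
  n_broad <- sum(fams$distribution == "broad")
  ab <- matrix(0, n, n_samples, dimnames = list(fams$cluster_id, samples))
  for (s in samples) {
    g <- groups[[s]]
    home <- which(fams$home_group == g)
    if (length(home)) {
      wt <- rgamma(length(home), shape = 2)
      ab[home, s] <- narrow_share * wt / sum(wt)
      ab[fams$distribution == "broad", s] <- (1 - narrow_share) / n_broad
    } else {
      ab[fams$distribution == "broad", s] <- 1 / n_broad
    }
  }
  ## per-gene coverage consistent with cluster abundance: split each
  ## cluster's abundance over its true member genes with fixed weights
  genes_by_fam <- split(sim$truth$genes$gene_id[!sim$truth$genes$is_intruder],
                        sim$truth$genes$family[!sim$truth$genes$is_intruder])
  glen <- setNames(nchar(sim$genes$sequence), sim$genes$id)
  cov_rows <- list()
  for (i in seq_len(n)) {
    gs <- genes_by_fam[[fams$family[i]]]
    wt <- rgamma(length(gs), shape = 5)
    wt <- wt / sum(wt)
    nzs <- samples[ab[i, ] > 0]
    if (!length(nzs)) next
    cov_rows[[i]] <- data.frame(
      gene_id = rep(gs, times = length(nzs)),
      sample = rep(nzs, each = length(gs)),
      coverage = as.vector(outer(wt * glen[gs], ab[i, nzs])),
      stringsAsFactors = FALSE)
  }
  coverage <- do.call(rbind, cov_rows)
  rownames(coverage) <- NULL
  gene_counts <- setNames(round(runif(n_samples, 8000, 12000)), samples)
  sim$truth$families <- fams
  list(coverage = coverage, gene_counts = gene_counts, groups = groups,
       abundance = ab, truth = sim$truth)
}

#' Simulate a rank-labelled genome tree with planted presence patterns
#'
#' A random coalescent bifurcating tree over `n_genomes` genomes, internal
#' nodes labelled with rank prefixes by relative depth. Lineage-specific
#' clusters are present in exactly one planted clade (2 tips to just under
#' half the genomes); cosmopolitan clusters are present in at least
#' `cosmo_min` of the genomes spread across clades.
#'
#' @param sim Output of earlier simulation stages (for cluster ids).
#' @param n_genomes Number of genome tips (>= 4, default 100).
#' @param ls_fraction Fraction of clusters planted lineage-specific
#'   (default 0.5).
#' @param cosmo_min Minimum prevalence of cosmopolitan clusters (default
#'   0.6).
#' @param seed Random seed.
#' @return List: `tree` (`phylo`), `presence` (named list cluster ->
#'   genomes), updated `truth` (`$families` gains `lineage_node`,
#'   `planted_tips`).
#' @export
simulate_tree_presence <- function(sim, n_genomes = 100L, ls_fraction = 0.5,
                                   cosmo_min = 0.6, seed = 1L) {
  stopifnot(n_genomes >= 4)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  tree <- ape::rcoal(n_genomes, tip.label = sprintf("G%03d",
                                                    seq_len(n_genomes)))
  nt <- n_genomes
  depths <- ape::node.depth.edgelength(tree)
  ndep <- depths[(nt + 1):(nt + tree$Nnode)]
  bins <- cut(ndep, breaks = quantile(ndep, seq(0, 1, length.out = 7),
                                      type = 7),
              include.lowest = TRUE, labels = FALSE)
  letters6 <- c("d", "p", "c", "o", "f", "g")
  tree$node.label <- sprintf("%s__N%03d", letters6[bins],
                             seq_len(tree$Nnode))
  sets <- .node_tipsets(tree)
  nodes <- (nt + 1):(nt + tree$Nnode)
  sizes <- lengths(sets[nodes])
  eligible <- nodes[sizes >= 2 & sizes < n_genomes / 2]
  fams <- sim$truth$families
  n <- nrow(fams)
  n_ls <- round(ls_fraction * n)
  fams$lineage_node <- NA_integer_
  presence <- vector("list", n)
  names(presence) <- fams$cluster_id
  for (i in seq_len(n)) {
    if (i <= n_ls) {
      nd <- sample(eligible, 1)
      fams$lineage_node[i] <- nd
      presence[[i]] <- tree$tip.label[sets[[nd]]]
    } else {
      k <- sample(seq(ceiling(cosmo_min * n_genomes), n_genomes), 1)
      presence[[i]] <- sort(sample(tree$tip.label, k))
    }
  }
  fams$planted_tips <- vapply(seq_len(n), function(i)
    paste(presence[[i]], collapse = ","), character(1))
  sim$truth$families <- fams
  list(tree = tree, presence = presence, truth = sim$truth)
}

#' Generate a full synthetic input bundle
#'
#' Convenience wrapper running all generator stages with sub-seeds derived
#' from one master seed.
#'
#' @param preset `"small"` (200 families x 20 genes) or `"medium"` (400 x
#'   30); individual parameters can be overridden via `...` (passed to
#'   [simulate_families()]).
#' @param seed Master seed.
#' @param noise Evidence corruption rate.
#' @param ... Overrides for [simulate_families()].
#' @return List with `genes`, `clusters`, `evidence`, `ecology`, `phylo`
#'   and the consolidated `truth`.
#' @export
simulate_dataset <- function(preset = c("small", "medium"), seed = 1L,
                             noise = 0, ...) {
  preset <- match.arg(preset)
  p <- switch(preset,
              small = list(n_families = 200L, genes_per_family = 20L),
              medium = list(n_families = 400L, genes_per_family = 30L))
  p <- modifyList(p, list(...))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  seeds <- sample.int(2^31 - 1, 4)
  sim <- do.call(simulate_families, c(p, list(seed = seeds[1])))
  ev <- simulate_evidence(sim, noise = noise, seed = seeds[2])
  sim$truth <- ev$truth
  eco <- simulate_ecology(sim, seed = seeds[3])
  sim$truth <- eco$truth
  phy <- simulate_tree_presence(sim, seed = seeds[4])
  sim$truth <- phy$truth
  list(genes = sim$genes, clusters = sim$clusters, evidence = ev,
       ecology = eco, phylo = phy, truth = sim$truth)
}
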