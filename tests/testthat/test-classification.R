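test_that("consensus architecture is the max-weight path with repeat collapse", {
  ## 2 complete genes A-B-C (weight 2 per edge) beat 1 incomplete A-B
  da <- consensus_da(list(g1 = c("A", "B", "C"), g2 = c("A", "B", "C"),
                          g3 = c("A", "B")),
                     c(g1 = TRUE, g2 = TRUE, g3 = FALSE))
  expect_equal(da, c("A", "B", "C"))
  ## consecutive repeats collapse
  expect_equal(consensus_da(list(g = c("A", "A", "B"))), c("A", "B"))
  ## single annotated gene: its own architecture
  expect_equal(consensus_da(list(g = c("X", "Y"))), c("X", "Y"))
  expect_error(consensus_da(list()), "no annotated")
  ## completeness tips the balance between equally frequent paths
  da2 <- consensus_da(list(g1 = c("A", "B"), g2 = c("A", "C")),
                      c(g1 = TRUE, g2 = FALSE))
  expect_equal(da2, c("A", "B"))
})

test_that("annotated clusters split into K and GU by the DUF rule", {
  expect_equal(classify_annotated(c("DUF123", "DUF456")), "GU")
  expect_equal(classify_annotated(c("DUF123", "PF00069")), "K")
  expect_equal(classify_annotated("PF00069"), "K")
  expect_equal(classify_annotated("PF999", duf_list = "PF999"), "GU")
  expect_error(classify_annotated(character(0)), "empty")
})

test_that("homolog filtering keeps hits within 60% of the log best e-value", {
  h <- data.frame(evalue = c(1e-100, 1e-70, 1e-30))
  expect_equal(filter_homologs(h)$evalue, c(1e-100, 1e-70))
  ## single hit survives
  expect_equal(nrow(filter_homologs(data.frame(evalue = 1e-8))), 1)
  ## best 1e-5 -> cutoff 3 -> 1e-3 retained
  h2 <- data.frame(evalue = c(1e-5, 1e-3, 1e-2))
  expect_equal(filter_homologs(h2)$evalue, c(1e-5, 1e-3))
  ## best hit always retained; retained set shrinks as the factor grows
  set.seed(8)
  for (i in 1:10) {
    h3 <- data.frame(evalue = 10^-runif(12, 1, 80))
    prev <- Inf
    for (f in c(0.2, 0.5, 0.8, 1.0)) {
      kept <- filter_homologs(h3, f)
      expect_true(min(h3$evalue) %in% kept$evalue)
      expect_lte(nrow(kept), prev)
      prev <- nrow(kept)
    }
  }
})

test_that("quorum vote requires a strict unknown majority", {
  mk <- function(anns) data.frame(target_annotation = anns,
                                  target_is_duf = FALSE)
  expect_equal(vote_category(mk(c(rep("hypothetical protein", 3), "kinase"))),
               "unknown")
  expect_equal(vote_category(mk(c("hypothetical protein", "uncharacterized",
                                  "kinase A", "kinase B"))), "known")  # tie
  expect_equal(vote_category(mk(c("ABC transporter", "polymerase"))), "known")
  ## DUF targets count as unknown evidence
  h <- data.frame(target_annotation = c("x", "y", "z"),
                  target_is_duf = c(TRUE, TRUE, FALSE))
  expect_equal(vote_category(h), "unknown")
})

test_that("unannotated clusters route through the nested search", {
  empty <- data.frame(target_annotation = character(0), evalue = numeric(0),
                      target_is_duf = logical(0))
  mk <- function(anns) data.frame(
    target_annotation = anns, evalue = 10^-seq(20, 20 + length(anns) - 1),
    target_is_duf = FALSE)
  expect_equal(classify_unannotated(empty, empty)$category, "EU")
  expect_equal(classify_unannotated(mk(rep("uncharacterized protein", 3)),
                                    empty)$category, "GU")
  expect_equal(classify_unannotated(empty,
                                    mk(rep("sulfatase", 3)))$category, "KWP")
})

test_that("EU refinement respects the 90% probability gate", {
  expect_equal(refine_eu(data.frame(probability = 0.92,
                                    target_annotation = "ABC transporter",
                                    target_is_duf = FALSE)), "KWP")
  expect_equal(refine_eu(data.frame(probability = 0.85,
                                    target_annotation = "ABC transporter",
                                    target_is_duf = FALSE)), "EU")
  expect_equal(refine_eu(data.frame(probability = c(0.95, 0.96),
                                    target_annotation = "hypothetical protein",
                                    target_is_duf = FALSE)), "GU")
  expect_equal(refine_eu(data.frame(probability = numeric(0),
                                    target_annotation = character(0),
                                    target_is_duf = logical(0))), "EU")
})

test_that("KWP refinement routes by probability, coverage and DUF status", {
  expect_equal(refine_kwp(data.frame(probability = 0.95, target_cov = 0.7,
                                     target = "PF00069")), "K")
  expect_equal(refine_kwp(data.frame(probability = 0.95, target_cov = 0.5,
                                     target = "PF00069")), "KWP")
  expect_equal(refine_kwp(data.frame(probability = 0.93, target_cov = 0.8,
                                     target = "DUF1234")), "GU")
  ## overlapping hits resolved by smaller e-value before routing
  h <- data.frame(probability = c(0.95, 0.95), target_cov = c(0.8, 0.8),
                  target = c("DUF1234", "PF00069"),
                  qstart = c(1, 5), qend = c(100, 95),
                  evalue = c(1e-30, 1e-10))
  expect_equal(refine_kwp(h), "GU")
})

test_that("refinement is monotone toward more known", {
  ## EU can only move to {EU, GU, KWP}; KWP only to {KWP, GU, K}
  set.seed(21)
  for (i in 1:20) {
    h <- data.frame(probability = runif(3), target_cov = runif(3),
                    target_annotation = sample(c("hypothetical protein",
                                                 "kinase"), 3, TRUE),
                    target_is_duf = FALSE,
                    target = sample(c("PF00001", "DUF999"), 3, TRUE))
    expect_true(refine_eu(h) %in% c("EU", "GU", "KWP"))
    expect_true(refine_kwp(h) %in% c("KWP", "GU", "K"))
  }
})

test_that("high-quality subset needs a complete representative and quorum", {
  mk <- function(comp_fracs, rep_complete) {
    n <- length(comp_fracs)
    genes <- list(); members <- list()
    for (i in seq_len(n)) {
      ids <- sprintf("c%d_g%d", i, 1:10)
      nc <- round(comp_fracs[i] * 10)
      comp <- c(rep(TRUE, nc), rep(FALSE, 10 - nc))
      if (rep_complete[i]) comp[1] <- TRUE else comp[1] <- FALSE
      genes[[i]] <- make_genes(setNames(rep(strrep("M", 30), 10), ids),
                               complete = comp)
      members[[i]] <- ids
    }
    g <- do.call(rbind, genes)
    class(g) <- c("gc_genes", "data.frame")
    cl <- gene_clusters(data.frame(
      representative = rep(sprintf("c%d_g1", seq_len(n)), each = 10),
      member = unlist(members)))
    select_high_quality(cl, g)
  }
  out <- mk(c(0.5, 0.5, 0.2), c(TRUE, FALSE, TRUE))
  expect_equal(out$is_high_quality[match(sprintf("c%d_g1", 1:3), out$id)],
               c(TRUE, FALSE, FALSE))
})

test_that("fragmented architectures collapse into larger ones", {
  out <- collapse_fragmented_das(list(c("A", "B"), c("A", "B", "C")),
                                 c(0.6, 0.9))
  expect_equal(out$assignment, c(1, 1))
  expect_length(out$das, 1)
  expect_equal(out$das[[1]], c("A", "B", "C"))

  out2 <- collapse_fragmented_das(list(c("A", "B"), c("A", "B", "C")),
                                  c(0.8, 0.9))
  expect_length(out2$das, 2)

  ## identical architectures deduplicate
  out3 <- collapse_fragmented_das(list(c("A", "B"), c("A", "B")), c(0.9, 0.9))
  expect_length(out3$das, 1)

  ## non-sub-architectures never collapse
  out4 <- collapse_fragmented_das(list(c("X", "B"), c("A", "B", "C")),
                                  c(0.1, 0.9))
  expect_length(out4$das, 2)
})

test_that("categories partition the validated clusters", {
  sim <- simulate_dataset("small", seed = 3, noise = 0,
                          n_families = 40L, genes_per_family = 12L)
  cl <- flag_small_clusters(sim$clusters)
  cls <- classify_clusters(cl, sim$evidence$domain_hits,
                           sim$evidence$uniref_hits, sim$evidence$nr_hits,
                           sim$genes)
  cats <- cls$clusters$category[!cls$clusters$flagged]
  expect_false(anyNA(cats))
  expect_true(all(cats %in% c("K", "KWP", "GU", "EU")))
  expect_equal(nrow(cls$decisions), sum(!cls$clusters$flagged))
})
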