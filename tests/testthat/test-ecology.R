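test_that("sample selection keeps counts at or above the first quartile", {
  expect_setequal(select_samples(c(a = 10, b = 20, c = 30, d = 40)),
                  c("b", "c", "d"))                      # Q1 = 17.5
  expect_setequal(select_samples(c(a = 5, b = 5, c = 5, d = 5)),
                  c("a", "b", "c", "d"))
  expect_setequal(select_samples(c(a = 1, b = 100, c = 100, d = 100)),
                  c("b", "c", "d"))                      # Q1 = 75.25
})

test_that("cluster abundance is length-normalized and TSS-scaled", {
  genes <- make_genes(c(g1 = strrep("M", 100), g2 = strrep("M", 50),
                        g3 = strrep("M", 100)))
  cl <- gene_clusters(data.frame(representative = c("g1", "g1", "g3"),
                                 member = c("g1", "g2", "g3")))
  cov <- data.frame(gene_id = c("g1", "g2", "g3"),
                    sample = "s1", coverage = c(200, 50, 100))
  ab <- cluster_abundance(cov, setNames(nchar(genes$sequence), genes$id), cl)
  ## gene abundances 2, 1, 1 -> clusters 3 and 1 -> TSS 0.75 / 0.25
  expect_equal(unname(ab[c("g1", "g3"), "s1"]), c(0.75, 0.25))
  expect_equal(sum(ab[, "s1"]), 1)
  ## absent gene contributes nothing: single cluster column is 1
  cov2 <- data.frame(gene_id = "g1", sample = "s2", coverage = 10)
  ab2 <- cluster_abundance(rbind(cov, cov2),
                           setNames(nchar(genes$sequence), genes$id), cl)
  expect_equal(unname(ab2["g1", "s2"]), 1)
  expect_error(cluster_abundance(cov, c(g1 = 0, g2 = 50, g3 = 100), cl),
               "zero length")
})

test_that("accumulation curve is a non-decreasing set union", {
  m <- matrix(0, 10, 2, dimnames = list(paste0("gc", 1:10), c("s1", "s2")))
  m[1:5, 1] <- 1; m[6:10, 2] <- 1
  acc <- accumulation_curve(m, n_perm = 20, seed = 1)
  expect_equal(acc$mean_gcs, c(5, 10))
  expect_equal(acc$sd_gcs[2], 0)
  ## general monotonicity
  set.seed(4)
  m2 <- matrix(rbinom(60, 1, 0.4), 12, 5)
  acc2 <- accumulation_curve(m2, n_perm = 30, seed = 2)
  expect_true(all(diff(acc2$mean_gcs) >= 0))
  ## single permutation, single sample: exact count
  acc3 <- accumulation_curve(m[, 1, drop = FALSE], n_perm = 1, seed = 1)
  expect_equal(acc3$mean_gcs, 5)
})

test_that("sample grouping recovers planted blocks and degenerate cases", {
  set.seed(9)
  base1 <- runif(30); base2 <- runif(30)
  mk <- function(base) base / sum(base)
  m <- cbind(sapply(1:4, function(i) mk(base1 + runif(30, 0, 0.01))),
             sapply(1:4, function(i) mk(base2 + runif(30, 0, 0.01))))
  colnames(m) <- paste0("s", 1:8)
  gr <- group_samples(m, min_size = 2)
  expect_equal(length(unique(gr)), 2)
  expect_equal(length(unique(gr[1:4])), 1)
  expect_equal(length(unique(gr[5:8])), 1)
  ## identical columns everywhere: one group
  m2 <- matrix(rep(mk(base1), 4), ncol = 4,
               dimnames = list(NULL, paste0("t", 1:4)))
  expect_equal(length(unique(group_samples(m2))), 1)
})

test_that("quasiswap nulls preserve both margin vectors exactly", {
  set.seed(5)
  m <- matrix(rpois(30, 4), 5, 6)
  nulls <- quasiswap_null(m, n_null = 20, seed = 3)
  for (x in nulls) {
    expect_equal(rowSums(x), rowSums(m))
    expect_equal(colSums(x), colSums(m))
    expect_true(all(x >= 0))
  }
  ## 1x1 margins force the matrix
  expect_equal(quasiswap_null(matrix(7L, 1, 1), 3, seed = 1)[[1]],
               matrix(7L, 1, 1))
  ## 2x2 identity: only the two margin-compatible states occur
  states <- vapply(quasiswap_null(diag(1L, 2), 200, seed = 2),
                   function(x) paste(x, collapse = ""), "")
  expect_setequal(unique(states), c("1001", "0110"))
  expect_error(quasiswap_null(matrix(c(0.5, 1, 1, 0.5), 2, 2)),
               "integer")
})

test_that("Levins niche breadth matches closed forms and is scale-invariant", {
  expect_equal(niche_breadth(rep(1, 4)), 4)
  expect_equal(niche_breadth(c(0, 0, 3, 0)), 1)
  expect_equal(niche_breadth(c(0.5, 0.5, 0, 0)), 2)
  set.seed(6)
  for (i in 1:10) {
    p <- runif(8)
    expect_equal(niche_breadth(p), niche_breadth(37.5 * p))
  }
  expect_error(niche_breadth(c(0, 0)), "all-zero")
})

test_that("distribution calls follow the quantile and tie rules", {
  ## observed below every null -> Narrow
  r1 <- classify_distribution(1.0, list(runif(100, 2, 4)))
  expect_equal(r1$call, "Narrow")
  ## observed at the null median -> Nonsignificant
  nulls <- seq(1, 3, length.out = 101)
  r2 <- classify_distribution(2.0, list(nulls))
  expect_equal(r2$call, "Nonsignificant")
  ## observed above every null -> Broad
  r3 <- classify_distribution(5.0, list(runif(100, 2, 4)))
  expect_equal(r3$call, "Broad")
  ## vote tie (Narrow, Broad) -> Nonsignificant
  r4 <- classify_distribution(c(1.0, 5.0),
                              list(runif(50, 2, 4), runif(50, 2, 4)))
  expect_equal(r4$call, "Nonsignificant")
  expect_equal(r4$votes, c("Narrow", "Broad"))
})

test_that("planted narrow/broad clusters are called correctly", {
  ## scaled-down version of the acceptance run (fewer clusters/datasets)
  sim <- simulate_families(n_families = 30, genes_per_family = 8, seed = 13)
  eco <- simulate_ecology(sim, n_samples = 12, n_groups = 3, seed = 13)
  glen <- setNames(nchar(sim$genes$sequence), sim$genes$id)
  ab <- cluster_abundance(eco$coverage, glen, sim$clusters)
  calls <- distribution_calls(ab, n_datasets = 4, n_null = 50, seed = 17)
  truth <- eco$truth$families
  tr <- truth$distribution[match(calls$gc_id, truth$cluster_id)]
  expect_gte(mean(calls$call[tr == "narrow"] == "Narrow"), 0.9)
  expect_gte(mean(calls$call[tr == "broad"] == "Broad"), 0.9)
})
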