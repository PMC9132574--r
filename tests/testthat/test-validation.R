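test_that("broken-stick threshold matches the closed form", {
  ## N = 3: E = ((1 + 1/2 + 1/3)/3, (1/2 + 1/3)/3, (1/3)/3)
  expect_equal(broken_stick_threshold(c(0.70, 0.20, 0.10)), 0.70)
  ## N = 2: E_1 = (1 + 1/2)/2 = 0.75
  expect_equal(broken_stick_threshold(c(0.9, 0.1)), 0.9)
  ## shares exactly equal to expectations: nothing strictly exceeds
  e3 <- rev(cumsum(1 / 3:1)) / 3
  expect_equal(broken_stick_threshold(e3), 0)
  ## scale invariance of the decision (values, not shares, returned)
  expect_equal(broken_stick_threshold(c(70, 20, 10)), 70)
  expect_error(broken_stick_threshold(c(0, 0, 0)), "all-zero")
})

test_that("resampling broken-stick variant agrees with closed form within one rank", {
  vals <- c(50, 25, 10, 8, 4, 2, 1)
  det <- broken_stick_threshold(vals)
  res <- broken_stick_threshold(vals, n_iter = 200, seed = 4)
  sorted <- sort(vals, decreasing = TRUE)
  expect_lte(abs(match(det, sorted) - match(res, sorted)), 1)
})

test_that("small clusters are flagged below the size threshold", {
  cl <- gene_clusters(data.frame(
    representative = rep(c("a1", "b1"), c(9, 10)),
    member = c(paste0("a", 1:9), paste0("b", 1:10))))
  cl <- flag_small_clusters(cl, 10)
  expect_equal(cl$flagged[match(c("a1", "b1"), cl$id)], c(TRUE, FALSE))
  cl1 <- flag_small_clusters(cl, 1)
  expect_false(any(cl1$flagged))
})

test_that("build_ssn makes a complete symmetric weighted graph", {
  s <- random_aa(60, seed = 1)
  g3 <- make_genes(c(x = s, y = s, z = s))
  ssn <- build_ssn(g3)
  expect_equal(igraph::ecount(ssn), 3)
  expect_equal(length(unique(igraph::E(ssn)$weight)), 1)

  g2 <- make_genes(c(x = s, y = random_aa(55, seed = 2)))
  expect_equal(igraph::ecount(build_ssn(g2)), 1)

  ## symmetry property: scorer order must not matter
  set.seed(5)
  for (i in 1:5) {
    a <- random_aa(sample(50:90, 1)); b <- random_aa(sample(50:90, 1))
    expect_equal(semiglobal_scorer(a, b), semiglobal_scorer(b, a))
  }
})

test_that("trim_ssn keeps the bottleneck of the maximum spanning tree", {
  g <- igraph::make_graph(~ a - b, b - c, a - c)
  igraph::E(g)$weight <- c(1, 2, 3)
  tg <- trim_ssn(g)
  expect_equal(sort(igraph::E(tg)$weight), c(2, 3))
  expect_true(igraph::is_connected(tg))

  ## a tree is untouched
  tr <- igraph::make_graph(~ a - b, b - c, c - d)
  igraph::E(tr)$weight <- c(5, 1, 3)
  expect_equal(igraph::ecount(trim_ssn(tr)), 3)

  dis <- igraph::make_graph(~ a - b, c - d)
  igraph::E(dis)$weight <- 1
  expect_error(trim_ssn(dis), "disconnected")

  ## oracle agreement on random graphs (full 200-seed sweep in acceptance)
  for (s in 1:30) {
    g <- random_connected_graph(s)
    tg <- trim_ssn(g)
    expect_true(igraph::is_connected(tg))
    expect_equal(igraph::vcount(tg), igraph::vcount(g))
    expect_equal(min(igraph::E(tg)$weight), oracle_trim_threshold(g))
  }
})

test_that("representative is the eigenvector-central node, ties lexicographic", {
  p <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  igraph::E(p)$weight <- 1
  expect_equal(select_representative(p), "c")

  single <- igraph::make_graph(NULL, n = 1) |> igraph::set_vertex_attr("name", value = "solo")
  expect_equal(select_representative(single), "solo")

  k <- igraph::make_full_graph(3)
  igraph::V(k)$name <- c("b", "a", "c")
  igraph::E(k)$weight <- 1
  expect_equal(select_representative(k), "a")

  ## permutation invariance
  set.seed(3)
  g <- random_connected_graph(17)
  r1 <- select_representative(g)
  perm <- sample(igraph::vcount(g))
  g2 <- igraph::permute(g, perm)
  expect_equal(select_representative(g2), r1)
})

test_that("MSA outlier screen flags the planted intruder and nothing else", {
  set.seed(7)
  root <- random_aa(80)
  seqs <- setNames(vapply(1:10, function(i) {
    ch <- strsplit(root, "")[[1]]
    flip <- sample(80, 4)
    ch[flip] <- sample(c("A", "G", "S", "T"), 4, TRUE)
    paste(ch, collapse = "")
  }, ""), paste0("m", 1:10))
  seqs["intruder"] <- random_aa(80)
  aln <- align_msa_naive(seqs)
  out <- detect_msa_outliers(aln, "m1")
  expect_equal(out, "intruder")

  same <- setNames(rep(root, 5), paste0("s", 1:5))
  expect_length(detect_msa_outliers(align_msa_naive(same), "s1"), 0)

  two <- setNames(c(root, random_aa(80)), c("a", "b"))
  expect_length(detect_msa_outliers(align_msa_naive(two), "a"), 0)

  expect_error(detect_msa_outliers(align_msa_naive(same), "nope"), "absent")
})

test_that("shadow genes are flagged by the overlap rules", {
  ## opposite strands, 70 bp overlap, lengths 300 / 900 -> short one flagged
  g <- data.frame(id = c("short", "long"), start = c(1, 231),
                  end = c(300, 1130), strand = c("+", "-"))
  expect_equal(flag_shadow_genes(g), "short")

  ## disjoint genes -> nothing
  g2 <- data.frame(id = c("a", "b"), start = c(1, 500), end = c(300, 800),
                   strand = c("+", "+"))
  expect_length(flag_shadow_genes(g2), 0)

  ## same strand, 10 bp overlap on 300 bp genes: below the 50% rule
  g3 <- data.frame(id = c("a", "b"), start = c(1, 291), end = c(300, 590),
                   strand = c("+", "+"))
  expect_length(flag_shadow_genes(g3), 0)

  ## same strand, 160/300 bp overlap -> shorter flagged
  g4 <- data.frame(id = c("a", "b"), start = c(1, 141), end = c(300, 500),
                   strand = c("+", "+"))
  expect_equal(flag_shadow_genes(g4), "a")

  ## equal lengths: larger start flagged
  g5 <- data.frame(id = c("a", "b"), start = c(1, 101), end = c(300, 400),
                   strand = c("+", "-"))
  expect_equal(flag_shadow_genes(g5), "b")
})

test_that("validate_clusters applies the discard rules and removals", {
  set.seed(11)
  root1 <- random_aa(90); root2 <- random_aa(100)
  mk_fam <- function(root, pre, n) {
    setNames(vapply(seq_len(n), function(i) {
      ch <- strsplit(root, "")[[1]]
      flip <- sample(length(ch), 3)
      ch[flip] <- sample(c("A", "G"), 3, TRUE)
      paste(ch, collapse = "")
    }, ""), paste0(pre, seq_len(n)))
  }
  seqs <- c(mk_fam(root1, "a", 10), mk_fam(root2, "b", 10))
  genes <- make_genes(seqs)
  cl <- gene_clusters(data.frame(
    representative = rep(c("a1", "b1"), each = 10), member = names(seqs)))

  ## shadow fraction 0.4 >= 0.30 discards cluster b
  val <- validate_clusters(cl, genes, shadow_ids = paste0("b", 1:4))
  expect_equal(val$report$decision[val$report$cluster_id == "b1"], "discard")
  expect_equal(val$clusters$category[val$clusters$id == "b1"], "DISCARDED")

  ## clean identical clusters are never discarded
  same <- make_genes(setNames(rep(root1, 12), paste0("s", 1:12)))
  cls <- gene_clusters(data.frame(representative = "s1",
                                  member = paste0("s", 1:12)))
  v2 <- validate_clusters(cls, same)
  expect_equal(v2$report$decision, "keep")
  expect_length(v2$clusters$members[[1]], 12)

  ## single spurious genes are removed from kept clusters
  v3 <- validate_clusters(cls, same, spurious_ids = "s5")
  expect_false("s5" %in% v3$clusters$members[[1]])
  expect_length(v3$clusters$members[[1]], 11)
})
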