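test_that("Jaccard distance matches its closed form", {
  expect_equal(jaccard_distance(c("A", "B"), c("A", "B")), 0)
  expect_equal(jaccard_distance(c("A", "B"), c("C", "D")), 1)
  expect_equal(jaccard_distance(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_error(jaccard_distance(character(0), "A"), "empty")
})

test_that("Jaccard distance satisfies the metric axioms on random triples", {
  set.seed(61)
  universe <- sprintf("g%02d", 1:15)
  for (i in 1:200) {
    s <- lapply(1:3, function(j) sample(universe, sample(2:8, 1)))
    d12 <- jaccard_distance(s[[1]], s[[2]])
    d13 <- jaccard_distance(s[[1]], s[[3]])
    d23 <- jaccard_distance(s[[2]], s[[3]])
    expect_equal(d12, jaccard_distance(s[[2]], s[[1]]))
    expect_equal(jaccard_distance(s[[1]], s[[1]]), 0)
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("complete linkage reproduces the hand-worked three-set example", {
  # engineered gene sets with d(1,2)=0.2, d(1,3)=0.9, d(2,3)>=0.8
  sets <- tibble::tibble(
    set_id = c("P1", "P2", "P3"),
    description = "d",
    genes = list(sprintf("g%02d", 1:10),
                 sprintf("g%02d", 1:8),
                 c(sprintf("g%02d", 10), sprintf("h%02d", 1:8)))
  )
  expect_equal(jaccard_distance(sets$genes[[1]], sets$genes[[2]]), 0.2)
  expect_gte(jaccard_distance(sets$genes[[1]], sets$genes[[3]]), 0.9)
  expect_gte(jaccard_distance(sets$genes[[2]], sets$genes[[3]]), 0.8)

  cl <- complete_linkage_cluster(sets, cutoff = 0.6)
  expect_equal(cl$members, list(c("P1", "P2"), "P3"))
  expect_equal(cl$height, c(0.2, 0))
})

test_that("degenerate cutoffs behave as specified", {
  sets <- tibble::tibble(
    set_id = c("P1", "P2", "P3"),
    description = "d",
    genes = list(c("A", "B"), c("A", "B"), c("C", "D"))
  )
  dup <- complete_linkage_cluster(sets, cutoff = 0)
  expect_equal(dup$members[[1]], c("P1", "P2"))  # identical sets always merge
  expect_equal(nrow(dup), 2L)

  distinct <- tibble::tibble(
    set_id = c("P1", "P2"), description = "d",
    genes = list(c("A", "B"), c("B", "C"))
  )
  expect_equal(nrow(complete_linkage_cluster(distinct, cutoff = 0)), 2L)
  expect_error(complete_linkage_cluster(distinct, cutoff = 1.2), "cutoff")
})

test_that("merge heights are non-decreasing and clusters respect the cut", {
  set.seed(62)
  universe <- sprintf("g%02d", 1:30)
  for (i in 1:30) {
    sets <- random_sets(sample(2:8, 1), universe)
    cl <- complete_linkage_cluster(sets, cutoff = 0.6)
    heights <- vapply(attr(cl, "merges"), `[[`, numeric(1), "height")
    expect_true(all(diff(heights) >= -1e-12))
    expect_true(all(cl$height <= ifelse(cl$n_members == 1, 0, 1)))
    expect_true(all(cl$height[cl$n_members > 1] <= 0.6 + 1e-12 |
                      cl$n_members == 1))
    expect_setequal(unlist(cl$members), sets$set_id)
  }
})

test_that("clustering agrees with hclust/cutree on tie-free instances", {
  set.seed(63)
  universe <- sprintf("g%03d", 1:40)
  for (i in 1:60) {
    n <- sample(3:6, 1)
    sets <- random_sets(n, universe, min_size = 5, max_size = 15)
    d <- outer(seq_len(n), seq_len(n), Vectorize(function(a, b) {
      jaccard_distance(sets$genes[[a]], sets$genes[[b]])
    }))
    low <- round(d[upper.tri(d)][d[upper.tri(d)] <= 0.6], 12)
    if (anyDuplicated(low)) next  # sub-cutoff ties: order is policy-defined
    cl <- complete_linkage_cluster(sets, cutoff = 0.6)
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    ref <- stats::cutree(hc, h = 0.6)
    ours <- integer(n)
    for (ci in seq_len(nrow(cl))) {
      ours[match(cl$members[[ci]], sets$set_id)] <- ci
    }
    # same partition up to label renaming
    expect_equal(length(unique(ours)), length(unique(ref)))
    expect_true(all(tapply(ref, ours, function(x) length(unique(x))) == 1))
  }
})

test_that("pooled differential genes are the flagged union of member sets", {
  sets <- tibble::tibble(
    set_id = c("P1", "P2"), description = "d",
    genes = list(c("A", "B"), c("B", "C"))
  )
  cl <- complete_linkage_cluster(sets, cutoff = 1)
  flags <- tibble::tibble(gene = c("A", "B", "C", "D"),
                          genotype = FALSE, oxygen = FALSE,
                          interaction = c(FALSE, TRUE, TRUE, TRUE))
  pooled <- pool_cluster_genes(cl, flags, effect = "interaction")
  expect_equal(pooled$pooled_genes[[1]], c("B", "C"))

  none <- tibble::tibble(gene = "Z", genotype = FALSE, oxygen = FALSE,
                         interaction = FALSE)
  expect_warning(pool_cluster_genes(cl, none), "no differential")

  # invariant to member order within the collection
  cl_rev <- complete_linkage_cluster(sets[2:1, ], cutoff = 1)
  pooled_rev <- pool_cluster_genes(cl_rev, flags, effect = "interaction")
  expect_setequal(pooled_rev$pooled_genes[[1]], pooled$pooled_genes[[1]])
})

test_that("the dendrogram exports as parseable newick", {
  skip_if_not_installed("ape")
  set.seed(64)
  sets <- random_sets(5, sprintf("g%02d", 1:25))
  cl <- complete_linkage_cluster(sets, cutoff = 0.6)
  tree <- ape::read.tree(text = cluster_newick(cl))
  expect_equal(sort(tree$tip.label), sort(sets$set_id))
})
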