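test_that("two haplotypes give a single edge and no medians", {
  h <- c(hap(id = "a", pop = "P1"), hap(DYS390 = 2, DYS439 = 1, id = "b",
                                        pop = "P1"))
  net <- build_network(h)
  expect_equal(nrow(net$profiles), 2)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$weight, 3)
  expect_false(any(net$kind == "median"))
})

test_that("a star triplet gains exactly the central median vector", {
  h <- c(hap(DYS390 = 1, id = "a"), hap(DYS439 = 1, id = "b"),
         hap(DYS19 = 1, id = "c"))
  net <- build_network(h)
  med <- net$profiles[net$kind == "median", , drop = FALSE]
  expect_equal(nrow(med), 1)
  expect_equal(unname(med[1, ]), unname(base_profile()))
  expect_equal(network_cost(net), 3) # vs 4 without the median
  # median nodes have degree >= 2
  mi <- which(net$kind == "median")
  expect_gte(sum(net$edges$from == mi | net$edges$to == mi), 2)
})

test_that("an observed haplotype already serving as median is reused", {
  h <- c(hap(id = "a"), hap(DYS390 = 1, id = "b"), hap(DYS390 = 2, id = "c"))
  net <- build_network(h)
  expect_equal(nrow(net$profiles), 3) # path a-b-c, no extra node
  expect_false(any(net$kind == "median"))
  expect_equal(nrow(net$edges), 2)
})

test_that("mixed haplogroups and trivial inputs are rejected", {
  expect_error(build_network(c(hap(), hap(haplogroup = "Q-M242"))),
               class = "ystr_validation_error")
  expect_error(build_network(reps(hap(), 3)),
               class = "ystr_validation_error")
})

test_that("network cost equals brute-force Steiner cost on tiny instances", {
  # instances small enough for exhaustive median enumeration: 4 varying loci
  mk <- function(...) hap(...)
  cases <- list(
    c(mk(DYS390 = 1), mk(DYS439 = 1), mk(DYS19 = 1)),
    c(mk(), mk(DYS390 = 1), mk(DYS390 = 2, DYS439 = 1)),
    c(mk(DYS390 = 1, DYS439 = 1), mk(DYS390 = 1), mk(DYS439 = 1), mk()),
    c(mk(DYS390 = 2), mk(DYS439 = 2), mk(DYS19 = 1), mk())
  )
  for (h in cases) {
    net <- build_network(h)
    vary <- apply(h$alleles, 2, function(v) length(unique(v)) > 1)
    keys <- apply(h$alleles, 1, paste, collapse = "-")
    prof <- h$alleles[!duplicated(keys), vary, drop = FALSE]
    expect_equal(network_cost(net), oracle_steiner_cost(prof),
                 info = paste("case with", length(h), "haplotypes"))
  }
})

test_that("medians never increase the connection cost (random fuzz)", {
  set.seed(77)
  for (i in 1:10) {
    n <- sample(4:7, 1)
    alle <- matrix(rep(base_profile(), each = n), n)
    colnames(alle) <- names(base_profile())
    vary <- sample(ncol(alle), 4)
    alle[, vary] <- alle[, vary] + matrix(sample(0:2, n * 4, TRUE), n)
    h <- str_haplotypes(alle, haplogroup = "X",
                        id = sprintf("f%d", seq_len(n)))
    if (length(unique(apply(alle, 1, paste, collapse = "-"))) < 2) next
    net <- build_network(h)
    D <- as.matrix(dist(unique(alle), method = "manhattan"))
    mst_obs <- sum(igraph::E(igraph::mst(
      igraph::graph_from_adjacency_matrix(D, weighted = TRUE,
                                          mode = "undirected")))$weight)
    expect_lte(network_cost(net), mst_obs + 1e-9)
  }
})

test_that("homoplasy-free genealogies are reconstructed exactly", {
  # founder plus single-step descendants at distinct loci: the true
  # genealogy collapsed to distinct haplotypes is a star around the founder
  h <- c(reps(hap(), 3, pop = "P1"),
         hap(DYS390 = 1, id = "d1", pop = "P1"),
         hap(DYS439 = -1, id = "d2", pop = "P1"),
         hap(DYS19 = 1, id = "d3", pop = "P1"))
  net <- build_network(h)
  expect_equal(nrow(net$profiles), 4)
  expect_false(any(net$kind == "median"))
  expect_equal(nrow(net$edges), 3)
  centre <- which(apply(net$profiles, 1, function(v)
    all(v == base_profile())))
  expect_true(all(net$edges$from == centre | net$edges$to == centre))
})

test_that("cluster delineation keeps the seed-population zone", {
  centre <- reps(hap(), 3, pop = "KAZ2")
  arms_in <- c(hap(DYS390 = 1, id = "i1", pop = "KAZ2"),
               hap(DYS439 = 1, id = "i2", pop = "KAZ2"),
               hap(DYS19 = 1, id = "i3", pop = "KAZ2"))
  net <- build_network(c(centre, arms_in))
  modal <- find_modal_haplotypes(c(centre, arms_in), threshold = 2)[[1]]
  cl <- delineate_cluster(net, "KAZ2", modal)
  expect_equal(cl$n_samples, 6) # all nodes belong to the seed population
  expect_equal(cl$enrichment, 1)

  # a foreign arm two steps out is excluded by the enrichment rule
  foreign <- c(reps(hap(DYS392 = 2), 4, pop = "UZB1"),
               reps(hap(DYS392 = 3), 4, pop = "UZB1"))
  net2 <- build_network(c(centre, arms_in, foreign))
  cl2 <- delineate_cluster(net2, "KAZ2", modal, enrichment_threshold = 0.5)
  expect_equal(cl2$n_samples, 6)
  expect_false(any(net2$profiles[cl2$members, "DYS392"] -
                     base_profile()["DYS392"] >= 2))

  # founder absent
  expect_error(delineate_cluster(net, "KAZ2",
                                 hap(DYS635 = 5, haplogroup = "C2b1a2-M48")),
               class = "ystr_validation_error")
})

test_that("distant haplotypes beyond the cap are ignored", {
  h <- c(reps(hap(), 3, pop = "P1"),
         hap(DYS390 = 3, id = "near", pop = "P1"),
         hap(DYS390 = 3, DYS439 = 3, id = "far", pop = "P1"))
  net <- build_network(h)
  modal <- find_modal_haplotypes(h, threshold = 2)[[1]]
  cl <- delineate_cluster(net, "P1", modal, distance_cap = 4)
  ids <- cl$member_ids
  expect_true(all(c("R001", "near") %in% ids))
  expect_false("far" %in% ids)
})

test_that("delineation is invariant to node insertion order", {
  h <- c(reps(hap(), 3, pop = "P1"),
         hap(DYS390 = 1, id = "x1", pop = "P1"),
         hap(DYS439 = 1, id = "x2", pop = "P2"),
         hap(DYS19 = 1, id = "x3", pop = "P1"),
         hap(DYS19 = 2, id = "x4", pop = "P2"))
  modal <- find_modal_haplotypes(h, threshold = 2)[[1]]
  cl1 <- delineate_cluster(build_network(h), "P1", modal)
  set.seed(13)
  perm <- sample(length(h))
  cl2 <- delineate_cluster(build_network(h[perm]), "P1", modal)
  expect_setequal(cl1$member_ids, cl2$member_ids)
  expect_equal(cl1$enrichment, cl2$enrichment)
})
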