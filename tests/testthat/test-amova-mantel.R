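mixed_design <- function() {
  # 2 groups x 2 populations x 6 samples, mixed haplogroups
  data.frame(
    population = rep(c("p1", "p2", "p3", "p4"), each = 6),
    haplogroup = c("A", "A", "A", "B", "B", "C",
                   "A", "B", "B", "B", "C", "C",
                   "C", "C", "C", "A", "D", "D",
                   "D", "D", "C", "C", "A", "D"))
}
scheme22 <- grouping_scheme("toy", c(p1 = "G1", p2 = "G1",
                                     p3 = "G2", p4 = "G2"))

test_that("monomorphic input yields zero components and a flag", {
  df <- data.frame(population = rep(c("p1", "p2", "p3", "p4"), each = 5),
                   haplogroup = "A")
  res <- amova(df, scheme22, n_perm = 49, seed = 1)
  expect_true(res$no_variation)
  expect_equal(unname(res$sigma2), c(0, 0, 0))
  expect_true(all(is.na(res$p_values)))
})

test_that("maximal between-group divergence puts 100% among groups", {
  df <- data.frame(population = rep(c("p1", "p2", "p3", "p4"), each = 5),
                   haplogroup = rep(c("A", "A", "B", "B"), each = 5))
  res <- amova(df, scheme22, n_perm = 99, seed = 2)
  expect_equal(res$pct_within_populations, 0, tolerance = 1e-9)
  expect_equal(res$pct_among_populations_within_groups, 0, tolerance = 1e-9)
  expect_equal(res$pct_among_groups, 100, tolerance = 1e-9)
  expect_equal(res$phi_st, 1)
})

test_that("components agree with the direct sums-of-squares oracle", {
  df <- mixed_design()
  res <- amova(df, scheme22, n_perm = 9, seed = 3)
  oracle <- oracle_amova(df$haplogroup, df$population, scheme22$assignment)
  expect_equal(unname(res$sigma2), unname(oracle), tolerance = 1e-9)
  pct <- c(res$pct_among_groups, res$pct_among_populations_within_groups,
           res$pct_within_populations)
  expect_equal(sum(pct), 100, tolerance = 1e-6)
})

test_that("percentages sum to 100 even with negative components", {
  # groups crossing the haplogroup split tend to produce a negative
  # among-group component, as happens in real data
  set.seed(9)
  found <- FALSE
  for (rep_i in 1:20) {
    df <- mixed_design()
    df$haplogroup <- sample(df$haplogroup)
    res <- amova(df, scheme22, n_perm = 9, seed = rep_i)
    pct <- c(res$pct_among_groups, res$pct_among_populations_within_groups,
             res$pct_within_populations)
    expect_equal(sum(pct), 100, tolerance = 1e-6)
    if (any(pct < 0)) found <- TRUE
  }
  expect_true(found)
})

test_that("AMOVA is invariant to sample order and haplogroup relabelling", {
  df <- mixed_design()
  res <- amova(df, scheme22, n_perm = 19, seed = 4)
  df2 <- df[rev(seq_len(nrow(df))), ]
  res2 <- amova(df2, scheme22, n_perm = 19, seed = 4)
  expect_equal(res$sigma2, res2$sigma2, tolerance = 1e-12)
  df3 <- df
  df3$haplogroup <- c(A = "Z9", B = "Q1", C = "M5", D = "K2")[df$haplogroup]
  res3 <- amova(df3, scheme22, n_perm = 19, seed = 4)
  expect_equal(res$sigma2, res3$sigma2, tolerance = 1e-12)
})

test_that("degenerate schemes are rejected", {
  df <- mixed_design()
  expect_error(grouping_scheme("one", c(p1 = "G", p2 = "G", p3 = "G",
                                        p4 = "G")),
               class = "ystr_validation_error")
  sch <- grouping_scheme("partial", c(p1 = "G1", p2 = "G2"))
  expect_error(amova(df, sch, n_perm = 9, seed = 1),
               class = "ystr_validation_error")
  expect_error(amova(df, scheme22, n_perm = 9),
               class = "ystr_validation_error") # seed mandatory
})

test_that("Mantel r hits exact endpoints", {
  m <- matrix(0, 3, 3); m[upper.tri(m)] <- c(1, 2, 3)
  m <- m + t(m)
  m2 <- matrix(0, 3, 3); m2[upper.tri(m2)] <- c(3, 2, 1)
  m2 <- m2 + t(m2)
  expect_equal(mantel(m, m, n_perm = 99, seed = 1)$r, 1)
  expect_equal(mantel(m, m2, n_perm = 99, seed = 1)$r, -1)
  expect_error(mantel(m, matrix(1, 3, 3) - diag(3), n_perm = 9, seed = 1),
               class = "ystr_validation_error")
})

test_that("Mantel agrees with full enumeration and vegan on n = 5", {
  set.seed(5)
  a <- as.matrix(dist(matrix(rnorm(10), 5)))
  b <- as.matrix(dist(matrix(rnorm(10), 5)))
  res <- mantel(a, b, n_perm = 999, seed = 6)
  oracle <- oracle_mantel_exact(a, b)
  expect_equal(res$r, oracle$r, tolerance = 1e-12)
  # permutation p within binomial error of the exact enumeration value
  se <- sqrt(oracle$p * (1 - oracle$p) / 999)
  expect_lt(abs(res$p_value - oracle$p), 4 * se + 2 / 1000)
  skip_if_not_installed("vegan")
  vg <- vegan::mantel(a, b, permutations = 99)
  expect_equal(res$r, unname(vg$statistic), tolerance = 1e-12)
})

test_that("Mantel permutation distribution is label-symmetric (r = 1 case)", {
  set.seed(8)
  a <- as.matrix(dist(matrix(rnorm(12), 6)))
  res <- mantel(a, a, n_perm = 199, seed = 9)
  expect_equal(res$r, 1)
  expect_lt(res$p_value, 0.05)
})
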