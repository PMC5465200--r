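test_that("a complete toy table round-trips with all fields populated", {
  path <- write_toy_table(list(toy_row("S1"), toy_row("S2", pop = "UZB1"),
                               toy_row("S3", dys389II = 30)))
  s <- read_sample_table(path)
  expect_s3_class(s, "ystr_samples")
  expect_equal(nrow(s), 3)
  expect_equal(s$sample_id, c("S1", "S2", "S3")) # row order preserved
  expect_equal(s$population, c("KAZ1", "UZB1", "KAZ1"))
  expect_equal(s$M217, rep("D", 3))
  expect_equal(s$DYS389II, c(31L, 31L, 30L))
  expect_false(anyNA(s$DYS390))
})

test_that("missing cells load as NA, not zero", {
  rows <- list(toy_row("S1"), toy_row("S2"))
  rows[[2]]$DYS389II <- NA
  rows[[2]]$M48 <- NA
  s <- read_sample_table(write_toy_table(rows))
  expect_true(is.na(s$DYS389II[2]))
  expect_true(is.na(s$M48[2]))
  expect_equal(s$DYS389II[1], 31L)
})

test_that("intermediate alleles are rejected naming sample and column", {
  rows <- list(toy_row("S1"), toy_row("S2", DYS390 = "23.2"))
  rows[[2]]$DYS390 <- "23.2"
  err <- expect_error(read_sample_table(write_toy_table(rows)),
                      class = "ystr_validation_error")
  expect_match(conditionMessage(err), "S2")
  expect_match(conditionMessage(err), "DYS390")
})

test_that("structural validation: duplicates, ranges, DYS389 ordering", {
  expect_error(read_sample_table(write_toy_table(
    list(toy_row("S1"), toy_row("S1")))), class = "ystr_validation_error")
  rows <- list(toy_row("S1")); rows[[1]]$DYS390 <- 99
  expect_error(read_sample_table(write_toy_table(rows)),
               class = "ystr_validation_error")
  expect_error(read_sample_table(write_toy_table(
    list(toy_row("S1", dys389I = 20, dys389II = 18)))),
    class = "ystr_validation_error")
  expect_error(read_sample_table(tempfile()), class = "ystr_io_error")
})

test_that("schema map renames dialect columns", {
  path <- write_toy_table(list(toy_row("S1")))
  txt <- readLines(path)
  txt[1] <- sub("sample_id", "Sample Name", txt[1])
  writeLines(txt, path)
  expect_error(read_sample_table(path), class = "ystr_schema_error")
  s <- read_sample_table(path, schema = c(sample_id = "Sample Name"))
  expect_equal(s$sample_id, "S1")
})

test_that("derive_haplotype computes DYS389b and flags duplicated DYS19", {
  s <- read_sample_table(write_toy_table(list(toy_row("S1"))))
  h <- derive_haplotype(s[1, ], "C2b1a2-M48")
  expect_equal(unname(h$alleles[1, "DYS389b"]), 17L) # 31 - 14
  expect_equal(unname(h$alleles[1, "DYS389I"]), 14L)
  expect_false(h$dys19_dup[1])
  expect_false(any(c("DYS385a", "DYS385b") %in% colnames(h$alleles)))

  s2 <- read_sample_table(write_toy_table(list(toy_row("S1", DYS19_2 = 17))))
  expect_true(derive_haplotype(s2[1, ], "C2b1a2-M48")$dys19_dup[1])

  # boundary: DYS389II == DYS389I gives DYS389b = 0
  s3 <- read_sample_table(write_toy_table(
    list(toy_row("S1", dys389I = 14, dys389II = 14))))
  expect_equal(unname(derive_haplotype(s3[1, ], "X")$alleles[1, "DYS389b"]),
               0L)
})

test_that("derive_haplotype errors identify the missing locus", {
  rows <- list(toy_row("S1")); rows[[1]]$DYS392 <- NA
  s <- read_sample_table(write_toy_table(rows))
  err <- expect_error(derive_haplotype(s[1, ], "X"),
                      class = "ystr_missing_locus_error")
  expect_match(conditionMessage(err), "DYS392")
})

test_that("derive_haplotypes excludes incomplete samples but keeps the rest", {
  rows <- list(toy_row("S1"), toy_row("S2"), toy_row("S3"))
  rows[[2]]$DYS635 <- NA
  s <- read_sample_table(write_toy_table(rows))
  h <- derive_haplotypes(s, "C2b1a2-M48")
  expect_equal(length(h), 2)
  expect_equal(attr(h, "excluded"), "S2")
})

test_that("write_results round-trips a frequency table and enforces pairings", {
  df <- data.frame(population = rep(c("A", "B"), c(4, 6)),
                   haplogroup = c(rep("H1", 3), "H2", rep("H2", 6)))
  ft <- frequency_table(df)
  path <- tempfile(fileext = ".tsv")
  write_results(ft, path, "tsv")
  back <- read.delim(path, check.names = FALSE)
  expect_equal(back$population, ft$populations)
  expect_equal(as.matrix(back[, ft$haplogroups]),
               unname(ft$p)[, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_error(write_results(ft, path, "graphml"),
               class = "ystr_unsupported_format")
})

test_that("graphml export carries node kinds and mutated-locus edge labels", {
  h <- c(hap(), hap(DYS390 = 1), hap(DYS439 = -1), hap(DYS390 = 1, DYS439 = 1))
  h$population <- c("KAZ1", "KAZ1", "KAZ2", "KAZ1")
  net <- build_network(h)
  path <- tempfile(fileext = ".graphml")
  write_results(net, path, "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_setequal(unique(igraph::V(g)$kind), unique(net$kind))
  expect_true(all(grepl("^(DYS|GATA)", igraph::E(g)$loci)))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})

test_that("amova json output contains components and p-values", {
  df <- data.frame(population = rep(c("p1", "p2", "p3", "p4"), each = 5),
                   haplogroup = rep(c("A", "B", "A", "B"), each = 5))
  res <- amova(df, grouping_scheme("s", c(p1 = "G1", p2 = "G1",
                                          p3 = "G2", p4 = "G2")),
               n_perm = 49, seed = 1)
  path <- tempfile(fileext = ".json")
  write_results(res, path, "json")
  parsed <- jsonlite::fromJSON(path)
  expect_length(parsed$sigma2, 3)
  expect_length(parsed$p_values, 3)
  expect_true(all(c("phi_ct", "phi_sc", "phi_st") %in%
                    names(parsed$p_values)))
})
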