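# fixture builders shared across test files; everything generated in code

base_profile <- function() {
  c(DYS389I = 14L, DYS389b = 17L, DYS390 = 25L, DYS456 = 15L, DYS19 = 16L,
    DYS458 = 17L, DYS437 = 14L, DYS438 = 10L, DYS448 = 20L, GATA_H4 = 10L,
    DYS391 = 10L, DYS392 = 11L, DYS393 = 13L, DYS439 = 11L, DYS635 = 23L)
}

# a haplotype `changes` steps away from base at the given loci,
# e.g. hap(DYS390 = +2, DYS19 = -1)
hap <- function(..., haplogroup = "C2b1a2-M48", id = NA, pop = NA,
                dys19_dup = FALSE) {
  p <- base_profile()
  ch <- list(...)
  for (nm in names(ch)) p[nm] <- p[nm] + ch[[nm]]
  str_haplotypes(p, haplogroup = haplogroup, dys19_dup = dys19_dup,
                 id = id, population = pop)
}

# n copies of a haplotype
reps <- function(h, n, pop = NA) {
  str_haplotypes(h$alleles[rep(1, n), , drop = FALSE], h$haplogroup[1],
                 h$dys19_dup[1], id = sprintf("R%03d", seq_len(n)),
                 population = pop)
}

# write a small raw sample table; rows = list of named lists
write_toy_table <- function(rows, path = tempfile(fileext = ".tsv")) {
  cols <- unique(unlist(lapply(rows, names)))
  lines <- vapply(rows, function(r) {
    paste(vapply(cols, function(cn) {
      v <- r[[cn]]
      if (is.null(v) || is.na(v)) "" else as.character(v)
    }, character(1)), collapse = "\t")
  }, character(1))
  writeLines(c(paste(cols, collapse = "\t"), lines), path)
  path
}

toy_row <- function(id, pop = "KAZ1", dys389I = 14, dys389II = 31, ...) {
  c(list(sample_id = id, population = pop, M217 = "D", M48 = "D",
         DYS389I = dys389I, DYS389II = dys389II, DYS390 = 25, DYS456 = 15,
         DYS19 = 16, DYS458 = 17, DYS437 = 14, DYS438 = 10, DYS448 = 20,
         GATA_H4 = 10, DYS391 = 10, DYS392 = 11, DYS393 = 13, DYS439 = 11,
         DYS635 = 23, DYS385a = 12, DYS385b = 14),
    list(...))
}
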