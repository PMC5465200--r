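#' Y-STR haplotype set
#'
#' Container for 15-locus integer STR profiles. Stored column-major as an
#' `n x 15` integer matrix (locus order fixed to [YSTR_15_LOCI]) together
#' with a haplogroup label, a duplicated-DYS19 flag and an optional sample id
#' and population per haplotype.
#'
#' @param alleles Integer matrix (or vector for a single haplotype) with 15
#'   columns; column names, if present, must equal [YSTR_15_LOCI].
#' @param haplogroup Character vector of haplogroup labels (recycled).
#' @param dys19_dup Logical, whether DYS19 is duplicated (recycled).
#' @param id Optional sample identifiers.
#' @param population Optional population codes.
#' @return An object of class `ystr_haplotypes`.
#' @examples
#' h <- str_haplotypes(rbind(c(14, 17, 25, 15, 16, 17, 14, 10, 20, 10,
#'                             10, 11, 13, 11, 23)), haplogroup = "C2b1a2-M48")
#' h
#' @export
str_haplotypes <- function(alleles, haplogroup = NA_character_,
                           dys19_dup = FALSE, id = NULL, population = NULL) {
  if (is.vector(alleles)) alleles <- matrix(alleles, nrow = 1)
  if (ncol(alleles) != length(YSTR_15_LOCI)) {
    ystr_abort(sprintf("haplotypes need exactly %d loci, got %d",
                       length(YSTR_15_LOCI), ncol(alleles)),
               "ystr_locus_error")
  }
  if (!is.null(colnames(alleles)) &&
      !identical(colnames(alleles), YSTR_15_LOCI)) {
    if (!setequal(colnames(alleles), YSTR_15_LOCI)) {
      ystr_abort("allele matrix column names do not match the 15-locus panel",
                 "ystr_locus_error")
    }
    alleles <- alleles[, YSTR_15_LOCI, drop = FALSE]
  }
  storage.mode(alleles) <- "integer"
  colnames(alleles) <- YSTR_15_LOCI
  rownames(alleles) <- NULL
  n <- nrow(alleles)
  if (n > 0 && (anyNA(alleles) || any(alleles < 0))) {
    ystr_abort("allele values must be non-negative integers (DYS389b may be 0)",
               "ystr_validation_error")
  }
  structure(list(
    alleles = alleles,
    haplogroup = rep_len(as.character(haplogroup), n),
    dys19_dup = rep_len(as.logical(dys19_dup), n),
    id = if (is.null(id)) rep(NA_character_, n) else
      rep_len(as.character(id), n),
    population = if (is.null(population)) rep(NA_character_, n) else
      rep_len(as.character(population), n)
  ), class = "ystr_haplotypes")
}

#' @export
length.ystr_haplotypes <- function(x) nrow(x$alleles)

#' @export
`[.ystr_haplotypes` <- function(x, i) {
  str_haplotypes(x$alleles[i, , drop = FALSE], x$haplogroup[i],
                 x$dys19_dup[i], x$id[i], x$population[i])
}

#' Concatenate haplotype sets
#' @param ... `ystr_haplotypes` objects.
#' @return A combined `ystr_haplotypes` object.
#' @export
c.ystr_haplotypes <- function(...) {
  xs <- list(...)
  str_haplotypes(do.call(rbind, lapply(xs, `[[`, "alleles")),
                 unlist(lapply(xs, `[[`, "haplogroup")),
                 unlist(lapply(xs, `[[`, "dys19_dup")),
                 unlist(lapply(xs, `[[`, "id")),
                 unlist(lapply(xs, `[[`, "population")))
}

#' @export
print.ystr_haplotypes <- function(x, ...) {
  cat(sprintf("<ystr_haplotypes: %d haplotype(s), %d loci>\n",
              length(x), ncol(x$alleles)))
  if (length(x)) {
    show <- head(data.frame(id = x$id, haplogroup = x$haplogroup,
                            dys19_dup = x$dys19_dup,
                            profile = apply(x$alleles, 1, paste,
                                            collapse = "-"),
                            stringsAsFactors = FALSE), 10)
    print(show, row.names = FALSE)
    if (length(x) > 10) cat(sprintf("... and %d more\n", length(x) - 10))
  }
  invisible(x)
}

# canonical string key of a profile (used for grouping identical haplotypes)
profile_key <- function(h) apply(h$alleles, 1, paste, collapse = "-")
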