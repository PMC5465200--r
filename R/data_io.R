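#' Read a Y-chromosome sample table
#'
#' Reads a TSV/CSV table with one row per sample: an identifier, a population
#' code, an optional clan label, SNP calls for any subset of the 35-marker
#' panel and raw Y-STR repeat counts (Yfiler 17-locus panel plus the optional
#' duplicated DYS19 copy `DYS19_2`).
#'
#' SNP call cells are coded `D`/`derived`/`+` (derived), `A`/`ancestral`/`-`
#' (ancestral); empty cells and `NA` mean untyped. STR cells must be integer
#' repeat counts in `[5, 60]`; empty cells mean missing. Intermediate
#' (non-integer) alleles such as `23.2` are rejected, not rounded: all
#' downstream step distances assume integer repeat states.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names (`sample_id`, `population`, `clan`, marker names, locus names) to
#'   the column names actually used in the file, to absorb export dialects.
#' @param sep Field separator; default tab, use `","` for CSV.
#' @return A `ystr_samples` data frame with canonical columns: `sample_id`,
#'   `population`, `clan`, one character column per typed SNP marker and one
#'   integer column per present STR locus. Row order is preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("sample_id\tpopulation\tM217\tDYS389I\tDYS389II",
#'              "S1\tKAZ1\tD\t14\t31"), tf)
#' read_sample_table(tf)
#' @export
read_sample_table <- function(path, schema = NULL, sep = "\t") {
  if (!file.exists(path)) {
    ystr_abort(sprintf("sample table not found: %s", path), "ystr_io_error")
  }
  raw <- read.delim(path, sep = sep, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (!is.null(schema)) {
    idx <- match(unname(schema), names(raw))
    if (anyNA(idx)) {
      ystr_abort(sprintf("schema columns absent from file: %s",
                         paste(unname(schema)[is.na(idx)], collapse = ", ")),
                 "ystr_schema_error")
    }
    names(raw)[idx] <- names(schema)
  }
  for (col in c("sample_id", "population")) {
    if (!col %in% names(raw)) {
      ystr_abort(sprintf("required column '%s' missing", col),
                 "ystr_schema_error")
    }
  }
  ids <- raw$sample_id
  if (anyNA(ids) || any(!nzchar(ids))) {
    ystr_abort("empty sample_id", "ystr_validation_error")
  }
  if (anyDuplicated(ids)) {
    ystr_abort(sprintf("duplicate sample_id: %s",
                       paste(unique(ids[duplicated(ids)]), collapse = ", ")),
               "ystr_validation_error")
  }
  if (anyNA(raw$population) || any(!nzchar(raw$population))) {
    ystr_abort(sprintf(
      "empty population code for sample(s): %s",
      paste(ids[is.na(raw$population) | !nzchar(raw$population)],
            collapse = ", ")), "ystr_validation_error")
  }

  out <- data.frame(sample_id = ids, population = raw$population,
                    clan = if ("clan" %in% names(raw)) raw$clan else
                      NA_character_,
                    stringsAsFactors = FALSE, check.names = FALSE)

  problems <- character(0)
  for (m in intersect(YSNP_MARKERS, names(raw))) {
    v <- raw[[m]]
    norm <- rep(NA_character_, length(v))
    norm[v %in% c("D", "d", "derived", "+")] <- "D"
    norm[v %in% c("A", "a", "ancestral", "-")] <- "A"
    bad <- !is.na(v) & is.na(norm)
    if (any(bad)) {
      problems <- c(problems, sprintf(
        "sample %s, column %s: invalid SNP call '%s'",
        ids[bad], m, v[bad]))
    }
    out[[m]] <- norm
  }
  for (loc in intersect(YSTR_RAW_LOCI, names(raw))) {
    v <- raw[[loc]]
    num <- suppressWarnings(as.numeric(v))
    bad_parse <- !is.na(v) & (is.na(num) | num != round(num))
    if (any(bad_parse)) {
      problems <- c(problems, sprintf(
        "sample %s, column %s: non-integer allele '%s'",
        ids[bad_parse], loc, v[bad_parse]))
    }
    intv <- ifelse(bad_parse, NA, suppressWarnings(as.integer(round(num))))
    oob <- !is.na(intv) & (intv < ALLELE_MIN | intv > ALLELE_MAX)
    if (any(oob)) {
      problems <- c(problems, sprintf(
        "sample %s, column %s: allele %d outside [%d, %d]",
        ids[oob], loc, intv[oob], ALLELE_MIN, ALLELE_MAX))
    }
    intv[oob] <- NA
    out[[loc]] <- as.integer(intv)
  }
  if (all(c("DYS389I", "DYS389II") %in% names(out))) {
    both <- !is.na(out$DYS389I) & !is.na(out$DYS389II)
    neg <- both & out$DYS389II < out$DYS389I
    if (any(neg)) {
      problems <- c(problems, sprintf(
        "sample %s: DYS389II (%d) < DYS389I (%d)",
        ids[neg], out$DYS389II[neg], out$DYS389I[neg]))
    }
  }
  if (length(problems)) {
    ystr_abort(paste0("sample table validation failed:\n  ",
                      paste(problems, collapse = "\n  ")),
               "ystr_validation_error")
  }
  class(out) <- c("ystr_samples", "data.frame")
  out
}

#' Read population metadata
#'
#' @param path TSV with columns `population`, `latitude`, `longitude` and one
#'   column per grouping scheme (for the Transoxiana design:
#'   `river_basin` in AmuDarya/SyrDarya, `altitude` in plain/foothill,
#'   `subsistence` in settled/nomadic).
#' @param sep Field separator.
#' @return A `ystr_meta` data frame.
#' @export
read_population_meta <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    ystr_abort(sprintf("metadata file not found: %s", path), "ystr_io_error")
  }
  meta <- read.delim(path, sep = sep, check.names = FALSE,
                     na.strings = c("NA", ""))
  for (col in c("population", "latitude", "longitude")) {
    if (!col %in% names(meta)) {
      ystr_abort(sprintf("required metadata column '%s' missing", col),
                 "ystr_schema_error")
    }
  }
  if (anyDuplicated(meta$population)) {
    ystr_abort("duplicate population codes in metadata",
               "ystr_validation_error")
  }
  bad <- is.na(meta$latitude) | is.na(meta$longitude) |
    abs(meta$latitude) > 90 | abs(meta$longitude) > 180
  if (any(bad)) {
    ystr_abort(sprintf("invalid coordinates for population(s): %s",
                       paste(meta$population[bad], collapse = ", ")),
               "ystr_validation_error")
  }
  class(meta) <- c("ystr_meta", "data.frame")
  meta
}

#' Derive the 15-locus analysis haplotype from raw Yfiler values
#'
#' Converts raw 17-locus typing into the analysis profile: `DYS389b` is
#' computed as `DYS389II - DYS389I` (DYS389II physically contains DYS389I),
#' the multi-copy loci DYS385a/b are dropped, and a duplicated DYS19
#' (`DYS19_2` present) is flagged so pairwise comparisons can exclude DYS19.
#'
#' @param record A one-row `ystr_samples` object (or named list) holding the
#'   raw STR columns.
#' @param haplogroup Haplogroup label to attach (e.g. from
#'   [assign_haplogroup()]).
#' @return A length-1 [str_haplotypes()] object.
#' @export
derive_haplotype <- function(record, haplogroup) {
  get1 <- function(loc) {
    v <- record[[loc]]
    if (is.null(v)) NA_integer_ else as.integer(v[1])
  }
  raw <- setNames(vapply(YSTR_RAW_LOCI, get1, integer(1)), YSTR_RAW_LOCI)
  missing_req <- YSTR_REQUIRED_RAW[is.na(raw[YSTR_REQUIRED_RAW])]
  if (length(missing_req)) {
    ystr_abort(sprintf("cannot derive haplotype, missing locus value(s): %s",
                       paste(missing_req, collapse = ", ")),
               "ystr_missing_locus_error")
  }
  if (raw["DYS389II"] < raw["DYS389I"]) {
    ystr_abort(sprintf("DYS389II (%d) < DYS389I (%d)",
                       raw["DYS389II"], raw["DYS389I"]),
               "ystr_validation_error")
  }
  alleles <- c(
    DYS389I = raw[["DYS389I"]],
    DYS389b = raw[["DYS389II"]] - raw[["DYS389I"]],
    raw[setdiff(YSTR_15_LOCI, c("DYS389I", "DYS389b"))]
  )
  id <- record[["sample_id"]]
  str_haplotypes(matrix(alleles, nrow = 1,
                        dimnames = list(NULL, YSTR_15_LOCI)),
                 haplogroup = haplogroup,
                 dys19_dup = !is.na(raw[["DYS19_2"]]),
                 id = if (is.null(id)) NA_character_ else as.character(id[1]))
}

#' Derive 15-locus haplotypes for a whole sample table
#'
#' Vectorised wrapper around the [derive_haplotype()] rules. Samples missing
#' any of the 15 required raw loci are excluded (they stay available for
#' haplogroup-frequency analyses) and reported in the `excluded` attribute.
#'
#' @param samples A `ystr_samples` table.
#' @param haplogroups Character vector of haplogroup labels, one per row
#'   (recycled if length 1).
#' @return A [str_haplotypes()] object with attribute `excluded` (character
#'   vector of dropped sample ids).
#' @export
derive_haplotypes <- function(samples, haplogroups) {
  n <- nrow(samples)
  haplogroups <- rep_len(haplogroups, n)
  get_col <- function(loc) {
    if (loc %in% names(samples)) as.integer(samples[[loc]])
    else rep(NA_integer_, n)
  }
  raw <- vapply(YSTR_RAW_LOCI, get_col, integer(n))
  if (n == 1L) raw <- matrix(raw, nrow = 1, dimnames = list(NULL, YSTR_RAW_LOCI))
  ok <- rowSums(is.na(raw[, YSTR_REQUIRED_RAW, drop = FALSE])) == 0
  ok <- ok & (raw[, "DYS389II"] >= raw[, "DYS389I"]) %in% TRUE
  excluded <- samples$sample_id[!ok]
  kept <- raw[ok, , drop = FALSE]
  alleles <- cbind(
    DYS389I = kept[, "DYS389I"],
    DYS389b = kept[, "DYS389II"] - kept[, "DYS389I"],
    kept[, setdiff(YSTR_15_LOCI, c("DYS389I", "DYS389b")), drop = FALSE]
  )[, YSTR_15_LOCI, drop = FALSE]
  out <- str_haplotypes(alleles,
                        haplogroup = haplogroups[ok],
                        dys19_dup = !is.na(kept[, "DYS19_2"]),
                        id = samples$sample_id[ok],
                        population = samples$population[ok])
  attr(out, "excluded") <- as.character(excluded)
  out
}

#' Write an analysis result to disk
#'
#' Deterministic text serialisation (sorted keys, 6 significant digits) for
#' the package's result types. Supported pairings: frequency tables,
#' distance matrices and ordinations as `tsv`; AMOVA, Mantel and age results
#' as `json`; median networks as `graphml`.
#'
#' @param obj A result object.
#' @param path Output file path.
#' @param format One of `"tsv"`, `"json"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_results <- function(obj, path, format = c("tsv", "json", "graphml")) {
  format <- match.arg(format)
  UseMethod("write_results")
}

unsupported <- function(obj, format) {
  ystr_abort(sprintf("format '%s' not supported for objects of class %s",
                     format, class(obj)[1]), "ystr_unsupported_format")
}

write_tsv_matrix <- function(m, path) {
  df <- data.frame(label = rownames(m),
                   apply(m, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_json_sorted <- function(x, path) {
  # sort keys recursively for byte-stable output
  srt <- function(v) {
    if (!is.list(v) && !is.null(names(v))) v <- as.list(v) # keep names
    if (is.list(v) && !is.null(names(v))) {
      v <- v[order(names(v))]
      lapply(v, srt)
    } else if (is.list(v)) lapply(v, srt) else v
  }
  jsonlite::write_json(srt(x), path, auto_unbox = TRUE, digits = 6,
                       pretty = TRUE, na = "null")
}

#' @export
write_results.ystr_freq <- function(obj, path, format = c("tsv", "json",
                                                          "graphml")) {
  format <- match.arg(format)
  if (format != "tsv") unsupported(obj, format)
  m <- obj$p
  df <- data.frame(population = rownames(m), n = obj$n,
                   apply(m, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.ystr_dist <- function(obj, path, format = c("tsv", "json",
                                                          "graphml")) {
  format <- match.arg(format)
  if (format != "tsv") unsupported(obj, format)
  write_tsv_matrix(obj$d, path)
  invisible(path)
}

#' @export
write_results.ystr_ordination <- function(obj, path,
                                          format = c("tsv", "json",
                                                     "graphml")) {
  format <- match.arg(format)
  if (format != "tsv") unsupported(obj, format)
  write_tsv_matrix(obj$coordinates, path)
  invisible(path)
}

#' @export
write_results.ystr_amova <- function(obj, path, format = c("tsv", "json",
                                                           "graphml")) {
  format <- match.arg(format)
  if (format != "json") unsupported(obj, format)
  write_json_sorted(unclass(obj), path)
  invisible(path)
}

#' @export
write_results.ystr_mantel <- function(obj, path, format = c("tsv", "json",
                                                            "graphml")) {
  format <- match.arg(format)
  if (format != "json") unsupported(obj, format)
  write_json_sorted(unclass(obj), path)
  invisible(path)
}

#' @export
write_results.ystr_age <- function(obj, path, format = c("tsv", "json",
                                                         "graphml")) {
  format <- match.arg(format)
  if (format != "json") unsupported(obj, format)
  write_json_sorted(unclass(obj), path)
  invisible(path)
}

#' @export
write_results.ystr_network <- function(obj, path, format = c("tsv", "json",
                                                             "graphml")) {
  format <- match.arg(format)
  if (format != "graphml") unsupported(obj, format)
  g <- as_igraph(obj)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @export
write_results.default <- function(obj, path, format = c("tsv", "json",
                                                        "graphml")) {
  format <- match.arg(format)
  if (format != "json" || !is.list(obj)) unsupported(obj, format)
  write_json_sorted(obj, path)
  invisible(path)
}
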