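#' Load a Y-SNP marker tree
#'
#' The marker tree gives, for each haplogroup label, its defining SNP and its
#' parent within the typed panel. The shipped default covers the package's
#' 35-marker panel with ISOGG-2016-style labels (only typed markers
#' participate; untyped intermediate ISOGG levels are not imputed). The file
#' is editable JSON so alternative or reduced panels can be supplied.
#'
#' @param path Path to a JSON array of `{label, parent, marker}` records;
#'   `parent = "Y"` denotes the root. Default: the shipped 35-marker tree.
#' @return A `ystr_tree` object: data frame with columns `label`, `parent`,
#'   `marker`, `depth`.
#' @export
marker_tree <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "marker_tree.json", package = "ystr")
  }
  df <- jsonlite::fromJSON(path)
  for (col in c("label", "parent", "marker")) {
    if (!col %in% names(df)) {
      ystr_abort(sprintf("marker tree missing field '%s'", col),
                 "ystr_schema_error")
    }
  }
  if (anyDuplicated(df$marker)) {
    ystr_abort("each marker may appear at exactly one node",
               "ystr_validation_error")
  }
  unknown <- setdiff(df$parent, c("Y", df$label))
  if (length(unknown)) {
    ystr_abort(sprintf("unknown parent label(s): %s",
                       paste(unknown, collapse = ", ")),
               "ystr_validation_error")
  }
  # depth by iterated parent lookup; also detects cycles
  depth <- rep(NA_integer_, nrow(df))
  for (i in seq_len(nrow(df))) {
    d <- 1L; p <- df$parent[i]
    while (p != "Y") {
      j <- match(p, df$label)
      d <- d + 1L
      p <- df$parent[j]
      if (d > nrow(df)) {
        ystr_abort("marker tree contains a cycle", "ystr_validation_error")
      }
    }
    depth[i] <- d
  }
  df$depth <- depth
  class(df) <- c("ystr_tree", "data.frame")
  df
}

#' Assign a haplogroup from SNP calls
#'
#' Returns the label of the deepest tree node whose marker is derived and all
#' of whose typed ancestors are also derived. When one or more child markers
#' of that node were typed ancestral, paragroup notation is used, e.g.
#' `C2*-M217(xM48)`. Markers that were not typed are treated as unknown, not
#' ancestral, so `(x...)` only ever names markers actually typed ancestral.
#'
#' @param snp_calls Named character vector over marker names with values
#'   `"D"` (derived), `"A"` (ancestral) or `NA` (untyped).
#' @param tree A [marker_tree()].
#' @return Haplogroup label string; `"unresolved"` when no typed marker is
#'   derived.
#' @examples
#' tr <- marker_tree()
#' assign_haplogroup(c(M217 = "D", M48 = "A"), tr) # "C2*-M217(xM48)"
#' @export
assign_haplogroup <- function(snp_calls, tree) {
  calls <- snp_calls[!is.na(snp_calls)]
  typed <- intersect(names(calls), tree$marker)
  if (!length(typed)) {
    ystr_abort("no tree marker typed", "ystr_validation_error")
  }
  state <- setNames(calls[typed], typed)
  derived <- names(state)[state == "D"]
  if (!length(derived)) return("unresolved")

  ancestors <- function(i) {
    out <- integer(0); p <- tree$parent[i]
    while (p != "Y") {
      j <- match(p, tree$label); out <- c(out, j); p <- tree$parent[j]
    }
    out
  }
  cand <- match(derived, tree$marker)
  for (i in cand) {
    anc <- ancestors(i)
    anc_typed_A <- tree$marker[anc][tree$marker[anc] %in% names(state) &
                                      state[tree$marker[anc]] == "A"]
    if (length(anc_typed_A)) {
      ystr_abort(sprintf(
        "inconsistent calls: %s derived but ancestral marker %s typed ancestral",
        tree$marker[i], paste(anc_typed_A, collapse = ", ")),
        "ystr_inconsistent_calls")
    }
  }
  best <- cand[order(-tree$depth[cand], tree$label[cand])][1]
  node <- tree[best, ]
  kids <- which(tree$parent == node$label)
  kid_A <- sort(tree$marker[kids][tree$marker[kids] %in% names(state) &
                                    state[tree$marker[kids]] == "A"])
  if (!length(kid_A)) return(node$label)
  base <- sub("-[^-]+$", "", node$label)
  sprintf("%s*-%s(x%s)", base, node$marker, paste(kid_A, collapse = ","))
}

#' Population-by-haplogroup frequency table
#'
#' @param x Data frame with a `haplogroup` column and the grouping column
#'   named by `by` (typically a `ystr_samples` table after assignment).
#' @param by Grouping column: `"population"` or `"clan"`.
#' @return A `ystr_freq` object: list with `populations`, `haplogroups`,
#'   matrix `p` of row-wise proportions (rows sum to 1), and sample sizes `n`.
#' @export
frequency_table <- function(x, by = c("population", "clan")) {
  by <- match.arg(by)
  if (!nrow(x)) ystr_abort("empty input", "ystr_validation_error")
  if (!"haplogroup" %in% names(x)) {
    ystr_abort("column 'haplogroup' required (run assignment first)",
               "ystr_schema_error")
  }
  keep <- !is.na(x[[by]]) & !is.na(x$haplogroup)
  x <- x[keep, , drop = FALSE]
  if (!nrow(x)) ystr_abort("no grouped records", "ystr_validation_error")
  tab <- table(x[[by]], x$haplogroup)
  counts <- matrix(tab, nrow = nrow(tab),
                   dimnames = list(rownames(tab), colnames(tab)))
  n <- rowSums(counts)
  structure(list(
    populations = rownames(counts),
    haplogroups = colnames(counts),
    p = counts / n,
    n = n
  ), class = "ystr_freq")
}

#' @export
print.ystr_freq <- function(x, ...) {
  cat(sprintf("<ystr_freq: %d group(s) x %d haplogroup(s)>\n",
              length(x$populations), length(x$haplogroups)))
  print(round(x$p, 3))
  invisible(x)
}

#' Haplogroup (gene) diversity
#'
#' Nei's unbiased gene diversity `HD = n (1 - sum p_i^2) / (n - 1)`:
#' the probability that two Y chromosomes drawn without replacement carry
#' different haplogroups. Applies equally to haplotype frequencies.
#'
#' @param p Frequency vector summing to 1.
#' @param n Sample size behind `p` (must be at least 2).
#' @return HD in `[0, 1]`.
#' @examples
#' haplogroup_diversity(c(0.8, 0.2), 10) # 0.3556
#' @export
haplogroup_diversity <- function(p, n) {
  if (n < 2) ystr_abort("HD undefined for n < 2", "ystr_validation_error")
  if (abs(sum(p) - 1) > 1e-9) {
    ystr_abort("frequencies must sum to 1", "ystr_validation_error")
  }
  n * (1 - sum(p^2)) / (n - 1)
}
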