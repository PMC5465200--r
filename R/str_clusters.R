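#' Mutational step distance between two haplotypes
#'
#' Sum over loci of absolute repeat-count differences — the natural metric
#' under the single-step mutation model. If either haplotype carries a
#' duplicated DYS19, the DYS19 locus is excluded from the comparison (no
#' per-copy matching is attempted) and the number of loci actually compared
#' is returned in the `loci_used` attribute.
#'
#' @param a,b Length-1 [str_haplotypes()] objects on the same 15-locus panel.
#' @return Non-negative integer distance with attribute `loci_used`.
#' @export
step_distance <- function(a, b) {
  if (!inherits(a, "ystr_haplotypes") || !inherits(b, "ystr_haplotypes") ||
      length(a) != 1 || length(b) != 1) {
    ystr_abort("step_distance expects two single haplotypes",
               "ystr_validation_error")
  }
  drop19 <- a$dys19_dup[1] || b$dys19_dup[1]
  loci <- if (drop19) setdiff(YSTR_15_LOCI, "DYS19") else YSTR_15_LOCI
  d <- sum(abs(a$alleles[1, loci] - b$alleles[1, loci]))
  structure(as.integer(d), loci_used = length(loci))
}

# full pairwise step-distance matrix; DYS19 excluded for pairs involving a
# duplicated-DYS19 haplotype, with distances rescaled by L/(L-1) for those
# pairs when `rescale` (keeps PD comparable across mixed sets)
step_dist_matrix <- function(h, rescale = FALSE) {
  D <- as.matrix(stats::dist(h$alleles, method = "manhattan"))
  if (any(h$dys19_dup)) {
    d19 <- abs(outer(h$alleles[, "DYS19"], h$alleles[, "DYS19"], "-"))
    mask <- outer(h$dys19_dup, h$dys19_dup, "|")
    D[mask] <- D[mask] - d19[mask]
    if (rescale) {
      L <- length(YSTR_15_LOCI)
      D[mask] <- D[mask] * L / (L - 1)
    }
  }
  D
}

#' Find modal haplotypes
#'
#' A modal haplotype is a 15-locus profile carried identically (within one
#' haplogroup) by more than `threshold` samples. Results are sorted by
#' descending carrier count, ties broken lexicographically by allele vector.
#'
#' @param haplotypes A [str_haplotypes()] set.
#' @param threshold Minimum carrier count; a profile qualifies when
#'   `count > threshold` (default 10, i.e. "more than 10 samples").
#' @return List of `ystr_modal` objects (possibly empty), each with fields
#'   `haplotype`, `count`, `threshold`.
#' @export
find_modal_haplotypes <- function(haplotypes, threshold = 10) {
  if (!length(haplotypes)) {
    ystr_abort("empty haplotype list", "ystr_validation_error")
  }
  key <- paste(haplotypes$haplogroup, profile_key(haplotypes),
               haplotypes$dys19_dup, sep = "|")
  counts <- table(key)
  qual <- names(counts)[counts > threshold]
  if (!length(qual)) return(list())
  first <- match(qual, key)
  ord <- do.call(order, c(list(-as.integer(counts[qual])),
                          lapply(seq_len(ncol(haplotypes$alleles)),
                                 function(j) haplotypes$alleles[first, j])))
  lapply(first[ord], function(i) {
    structure(list(haplotype = haplotypes[i],
                   count = as.integer(counts[[key[i]]]),
                   threshold = threshold),
              class = "ystr_modal")
  })
}

#' @export
print.ystr_modal <- function(x, ...) {
  cat(sprintf("<ystr_modal: %s, %d carrier(s) (threshold %d)>\n  %s\n",
              x$haplotype$haplogroup[1], x$count, x$threshold,
              paste(x$haplotype$alleles[1, ], collapse = "-")))
  invisible(x)
}

#' Search a haplotype database for relatives of a modal haplotype
#'
#' Returns every database haplotype of the same haplogroup within `radius`
#' mutational steps of the modal haplotype (exact matches included). The
#' default radius 4 encodes "fewer than 5 mutational steps".
#'
#' @param modal A `ystr_modal` (or length-1 [str_haplotypes()]).
#' @param database A [str_haplotypes()] set with haplogroup labels.
#' @param radius Maximum step distance (inclusive).
#' @return A `ystr_related` object with fields `modal`, `members`
#'   (a [str_haplotypes()] subset), `radius`, `n`.
#' @export
related_search <- function(modal, database, radius = 4) {
  hap <- if (inherits(modal, "ystr_modal")) modal$haplotype else modal
  joint <- c(hap, database)
  D <- step_dist_matrix(joint)
  d <- D[1, -1]
  sel <- database$haplogroup == hap$haplogroup[1] & d <= radius
  sel[is.na(sel)] <- FALSE
  structure(list(modal = modal, members = database[sel],
                 radius = radius, n = sum(sel)),
            class = "ystr_related")
}

#' @export
print.ystr_related <- function(x, ...) {
  cat(sprintf("<ystr_related: %d haplotype(s) within %d step(s)>\n",
              x$n, x$radius))
  invisible(x)
}

#' Within-lineage diversity statistics
#'
#' `PD`: mean pairwise step distance over all unordered pairs (pairs
#' involving a duplicated DYS19 compare 14 loci and are rescaled by 15/14).
#' `HD`: haplotype diversity `n (1 - sum q_k^2) / (n - 1)` over distinct
#' profile frequencies.
#'
#' @param haplotypes A [str_haplotypes()] set with `n >= 2`.
#' @return A `ystr_lineage_stats` list with `HD`, `PD`, `n`.
#' @export
lineage_stats <- function(haplotypes) {
  n <- length(haplotypes)
  if (n < 2) ystr_abort("lineage statistics need n >= 2",
                        "ystr_validation_error")
  D <- step_dist_matrix(haplotypes, rescale = TRUE)
  pd <- mean(D[upper.tri(D)])
  q <- as.numeric(table(profile_key(haplotypes))) / n
  hd <- n * (1 - sum(q^2)) / (n - 1)
  structure(list(HD = hd, PD = pd, n = n), class = "ystr_lineage_stats")
}

#' @export
print.ystr_lineage_stats <- function(x, ...) {
  cat(sprintf("<ystr_lineage_stats: n = %d, HD = %.3f, PD = %.3f>\n",
              x$n, x$HD, x$PD))
  invisible(x)
}
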