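#' Grouping scheme for AMOVA
#'
#' @param name Scheme name (`river_basin`, `altitude`, `subsistence`, or any
#'   label).
#' @param assignment Named character vector: population code -> group label.
#' @return A `ystr_scheme` object.
#' @export
grouping_scheme <- function(name, assignment) {
  if (length(unique(assignment)) < 2) {
    ystr_abort("a grouping scheme needs at least 2 groups",
               "ystr_validation_error")
  }
  structure(list(name = name, assignment = assignment),
            class = "ystr_scheme")
}

#' Three-level AMOVA on haplogroup assignments
#'
#' Partitions molecular variance among groups of populations, among
#' populations within groups, and within populations, using the 0/1
#' haplogroup distance (two samples differ iff their haplogroups differ).
#' Variance components follow the nested sums-of-squares decomposition with
#' unequal sample-size coefficients; negative components are retained, so the
#' three percentages always sum to 100. Phi statistics:
#' `Phi_CT = s2a/tot`, `Phi_SC = s2b/(s2b + s2c)`, `Phi_ST = (s2a + s2b)/tot`.
#'
#' Permutation p-values (one per Phi statistic): whole populations permuted
#' across groups for `Phi_CT`; individuals permuted across populations within
#' their group for `Phi_SC`; individuals permuted across all populations for
#' `Phi_ST`. `p = (#\{perm >= observed\} + 1) / (n_perm + 1)`.
#'
#' @param records Data frame with columns `haplogroup` and `population`.
#' @param scheme A [grouping_scheme()] assigning every analysed population to
#'   a group.
#' @param n_perm Number of permutations per test (default 9999).
#' @param seed Integer seed (mandatory; the caller's RNG state is restored).
#' @return A `ystr_amova` object: sigma2, percentages, Phi statistics,
#'   p-values, df, and a `no_variation` flag.
#' @export
amova <- function(records, scheme, n_perm = 9999, seed) {
  if (missing(seed)) ystr_abort("seed is mandatory", "ystr_validation_error")
  keep <- !is.na(records$haplogroup) & !is.na(records$population)
  records <- records[keep, , drop = FALSE]
  pops <- sort(unique(records$population))
  unassigned <- setdiff(pops, names(scheme$assignment))
  if (length(unassigned)) {
    ystr_abort(sprintf("population(s) not assigned to a group: %s",
                       paste(unassigned, collapse = ", ")),
               "ystr_validation_error")
  }
  g_of_p <- scheme$assignment[pops]
  if (length(unique(g_of_p)) < 2) {
    ystr_abort("scheme degenerates to a single group over these populations",
               "ystr_validation_error")
  }
  pop <- match(records$population, pops)
  hg <- match(records$haplogroup, sort(unique(records$haplogroup)))
  K <- max(hg)
  P <- length(pops)
  grp <- match(g_of_p, sort(unique(g_of_p)))
  G <- max(grp)
  n_p <- tabulate(pop, P)
  if (any(n_p < 2)) {
    ystr_abort(sprintf("populations need >= 2 samples (violated by: %s)",
                       paste(pops[n_p < 2], collapse = ", ")),
               "ystr_validation_error")
  }

  comp_obs <- amova_components(pop, hg, grp, P, K, G)
  tot <- sum(comp_obs$sigma2)
  no_var <- tot <= 0 && all(abs(comp_obs$sigma2) < 1e-12)

  perms <- with_seed(seed, {
    r_ct <- r_sc <- r_st <- 0L
    if (!no_var) {
      for (b in seq_len(n_perm)) {
        # Phi_CT: permute whole populations across groups
        if (!is.nan(comp_obs$phi_ct)) {
          cct <- amova_components(pop, hg, sample(grp), P, K, G)
          if (!is.nan(cct$phi_ct) && cct$phi_ct >= comp_obs$phi_ct - 1e-12)
            r_ct <- r_ct + 1L
        }
        # Phi_SC: permute individuals across populations within groups
        if (!is.nan(comp_obs$phi_sc)) {
          hg_sc <- hg
          for (g in seq_len(G)) {
            idx <- which(grp[pop] == g)
            if (length(idx) > 1) hg_sc[idx] <- hg_sc[sample(idx)]
          }
          csc <- amova_components(pop, hg_sc, grp, P, K, G)
          if (!is.nan(csc$phi_sc) && csc$phi_sc >= comp_obs$phi_sc - 1e-12)
            r_sc <- r_sc + 1L
        }
        # Phi_ST: permute individuals across all populations
        if (!is.nan(comp_obs$phi_st)) {
          cst <- amova_components(pop, sample(hg), grp, P, K, G)
          if (!is.nan(cst$phi_st) && cst$phi_st >= comp_obs$phi_st - 1e-12)
            r_st <- r_st + 1L
        }
      }
    }
    c(ct = r_ct, sc = r_sc, st = r_st)
  })
  pv <- (perms + 1) / (n_perm + 1)
  pv[c(is.nan(comp_obs$phi_ct), is.nan(comp_obs$phi_sc),
       is.nan(comp_obs$phi_st)) | no_var] <- NA_real_

  pct <- if (no_var) rep(NaN, 3) else 100 * comp_obs$sigma2 / tot
  structure(list(
    scheme = scheme$name,
    sigma2 = setNames(comp_obs$sigma2,
                      c("among_groups", "among_populations_within_groups",
                        "within_populations")),
    pct_among_groups = pct[1],
    pct_among_populations_within_groups = pct[2],
    pct_within_populations = pct[3],
    phi_ct = comp_obs$phi_ct, phi_sc = comp_obs$phi_sc,
    phi_st = comp_obs$phi_st,
    p_values = setNames(as.numeric(pv), c("phi_ct", "phi_sc", "phi_st")),
    n_permutations = n_perm,
    df = comp_obs$df,
    no_variation = no_var
  ), class = "ystr_amova")
}

# variance components from integer-coded vectors; core of both the observed
# statistic and the permutation loop, so it must stay cheap: all sums of
# squares reduce to haplogroup counts because the 0/1 distance satisfies
# SSD(S) = (n^2 - sum_k c_k^2) / (2 n)
amova_components <- function(pop, hg, grp, P, K, G) {
  N <- length(pop)
  cnt <- tabulate(pop + P * (hg - 1L), P * K) # P x K counts, column-major
  dim(cnt) <- c(P, K)
  n_p <- tabulate(pop, P)
  N_g <- tabulate(grp, G)[seq_len(G)] # pops per group
  n_g <- as.vector(rowsum(n_p, grp))  # samples per group
  ssd <- function(c2sum, n) (n^2 - c2sum) / (2 * n)

  c2_pop <- rowSums(cnt^2)
  cnt_g <- rowsum(cnt, grp)
  c2_grp <- rowSums(cnt_g^2)
  c2_tot <- sum(colSums(cnt)^2)

  ssd_wp <- sum(ssd(c2_pop, n_p))
  ssd_g <- ssd(c2_grp, n_g)
  ssd_ap <- sum(ssd_g) - ssd_wp
  ssd_ag <- ssd(c2_tot, N) - sum(ssd_g)

  df_ag <- G - 1
  df_ap <- P - G
  df_wp <- N - P
  ms_wp <- ssd_wp / df_wp
  ms_ag <- ssd_ag / df_ag

  npg2 <- as.vector(rowsum(n_p^2, grp))
  n2 <- (sum(npg2 / n_g) - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag

  s2c <- ms_wp
  if (df_ap > 0) {
    # among-populations-within-groups level exists
    ms_ap <- ssd_ap / df_ap
    n1 <- (N - sum(npg2 / n_g)) / df_ap
    s2b <- (ms_ap - s2c) / n1
  } else {
    # every group holds a single population: the level vanishes
    s2b <- 0
  }
  s2a <- (ms_ag - s2c - n2 * s2b) / n3
  tot <- s2a + s2b + s2c
  list(sigma2 = c(s2a, s2b, s2c),
       phi_ct = if (!is.na(tot) && tot != 0) s2a / tot else NaN,
       phi_sc = if (df_ap > 0 && (s2b + s2c) != 0) s2b / (s2b + s2c)
                else NaN,
       phi_st = if (!is.na(tot) && tot != 0) (s2a + s2b) / tot else NaN,
       df = c(among_groups = df_ag, among_populations = df_ap,
              within_populations = df_wp))
}

#' @export
print.ystr_amova <- function(x, ...) {
  cat(sprintf("<ystr_amova: scheme '%s'>\n", x$scheme))
  if (x$no_variation) cat("no variation in the data\n")
  tab <- data.frame(
    source = c("Among groups", "Among populations within groups",
               "Within populations"),
    sigma2 = round(unname(x$sigma2), 5),
    pct = round(c(x$pct_among_groups,
                  x$pct_among_populations_within_groups,
                  x$pct_within_populations), 2))
  print(tab, row.names = FALSE)
  cat(sprintf("Phi_CT = %.4f (p = %.4g), Phi_SC = %.4f (p = %.4g), Phi_ST = %.4f (p = %.4g)\n",
              x$phi_ct, x$p_values["phi_ct"], x$phi_sc, x$p_values["phi_sc"],
              x$phi_st, x$p_values["phi_st"]))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the upper-triangle entries, with significance by
#' joint row/column permutation of one matrix. Two-sided:
#' `p = (#\{|r_perm| >= |r_obs|\} + 1) / (n_perm + 1)`.
#'
#' @param dg,dgeo `ystr_dist` objects (or matrices) with identical labels in
#'   identical order and finite entries.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed (mandatory).
#' @return A `ystr_mantel` object with `r`, `p_value`, `n_permutations`.
#' @export
mantel <- function(dg, dgeo, n_perm = 999, seed) {
  if (missing(seed)) ystr_abort("seed is mandatory", "ystr_validation_error")
  m1 <- if (inherits(dg, "ystr_dist")) dg$d else as.matrix(dg)
  m2 <- if (inherits(dgeo, "ystr_dist")) dgeo$d else as.matrix(dgeo)
  if (!identical(dim(m1), dim(m2)) ||
      (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
       !identical(rownames(m1), rownames(m2)))) {
    ystr_abort("matrices must share labels in the same order",
               "ystr_validation_error")
  }
  if (any(!is.finite(m1)) || any(!is.finite(m2))) {
    ystr_abort("matrices must be finite", "ystr_validation_error")
  }
  ut <- upper.tri(m1)
  x <- m1[ut]; y <- m2[ut]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    ystr_abort("zero variance in a distance triangle: r undefined",
               "ystr_validation_error")
  }
  r_obs <- cor(x, y)
  n <- nrow(m1)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample(n)
      rp <- cor(x, m2[idx, idx][ut])
      if (abs(rp) >= abs(r_obs) - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  structure(list(r = r_obs, p_value = (exceed + 1) / (n_perm + 1),
                 n_permutations = n_perm, two_sided = TRUE),
            class = "ystr_mantel")
}

#' @export
print.ystr_mantel <- function(x, ...) {
  cat(sprintf("<ystr_mantel: r = %.4f, p = %.4g (%d permutations)>\n",
              x$r, x$p_value, x$n_permutations))
  invisible(x)
}
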