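#' Stepwise mutation model parameters
#'
#' Defaults follow the "genealogical" Y-STR calibration: mutation rate
#' `mu = 2.1e-3` per locus per generation, male generation time `g = 30`
#' years, `L = 15` loci.
#'
#' @param mu Mutation rate per locus per generation.
#' @param g Generation time in years.
#' @param L Number of STR loci in the profile.
#' @return A `ystr_params` object.
#' @export
mutation_model <- function(mu = 2.1e-3, g = 30, L = 15) {
  if (mu <= 0 || g <= 0 || L < 1) {
    ystr_abort("require mu > 0, g > 0, L >= 1", "ystr_validation_error")
  }
  structure(list(mu = mu, g = g, L = L), class = "ystr_params")
}

# per-sample step distances to the founder; pairs with a duplicated DYS19
# compare 14 loci and are rescaled to the full panel
founder_distances <- function(haplotypes, founder) {
  if (!inherits(founder, "ystr_haplotypes") || length(founder) != 1) {
    ystr_abort("founder must be a single haplotype", "ystr_validation_error")
  }
  if (!identical(colnames(founder$alleles), colnames(haplotypes$alleles))) {
    ystr_abort("founder locus set does not match the haplotypes",
               "ystr_locus_error")
  }
  joint <- c(founder, haplotypes)
  D <- step_dist_matrix(joint, rescale = TRUE)
  D[1, -1]
}

#' Rho-statistic TMRCA of a descent cluster
#'
#' `rho` is the mean number of mutational steps separating each sampled
#' haplotype from the founder; under the single-step model it accumulates at
#' `L * mu` per generation, so `age = rho / (L mu) * g` years. The standard
#' deviation uses the branch formula
#' `sigma_rho^2 = (1/n^2) sum_b c_b^2 m_b` over the network rooted at the
#' founder (`c_b` = sampled haplotypes whose root path uses branch `b`,
#' `m_b` = mutations on `b`) when a network is supplied; without one a star
#' genealogy is assumed, giving `sigma_rho^2 = rho / n`.
#'
#' @param haplotypes A [str_haplotypes()] set (the cluster members; carriers
#'   of the founder profile included).
#' @param founder Length-1 [str_haplotypes()] (or `ystr_modal`).
#' @param net Optional `ystr_network` containing the founder, for the
#'   branch-based standard deviation.
#' @param params A [mutation_model()].
#' @return A `ystr_age` object with `rho`, `sigma_rho`, `age_rho_years`,
#'   `sd_rho_years`, `n`, `sigma_method`.
#' @export
rho_age <- function(haplotypes, founder, net = NULL,
                    params = mutation_model()) {
  if (inherits(founder, "ystr_modal")) founder <- founder$haplotype
  n <- length(haplotypes)
  if (n < 1) ystr_abort("need at least one haplotype",
                        "ystr_validation_error")
  d <- founder_distances(haplotypes, founder)
  rho <- mean(d)
  if (is.null(net)) {
    sigma2 <- rho / n
    method <- "star"
  } else {
    sigma2 <- saillard_sigma2(net, founder)
    method <- "network_branches"
  }
  per_gen <- params$L * params$mu
  structure(list(
    rho = rho, sigma_rho = sqrt(sigma2),
    age_rho_years = rho / per_gen * params$g,
    sd_rho_years = sqrt(sigma2) / per_gen * params$g,
    n = n, sigma_method = method,
    mu = params$mu, generation_years = params$g, n_loci = params$L
  ), class = "ystr_age")
}

# Saillard-style variance on the shortest-path tree rooted at the founder
saillard_sigma2 <- function(net, founder) {
  node_keys <- apply(net$profiles, 1, paste, collapse = "-")
  f <- match(paste(founder$alleles[1, ], collapse = "-"), node_keys)
  if (is.na(f)) {
    ystr_abort("founder haplotype not present in the network",
               "ystr_validation_error")
  }
  sp <- shortest_paths_det(net, f)
  n_nodes <- nrow(net$profiles)
  nsamp <- sum(net$multiplicity[is.finite(sp$dist)])
  # subtree sample counts: process nodes by decreasing distance
  sub <- as.numeric(net$multiplicity)
  ord <- order(-sp$dist)
  s2 <- 0
  for (v in ord) {
    if (v == f || !is.finite(sp$dist[v])) next
    p <- sp$parent[v]
    m_b <- sp$dist[v] - sp$dist[p]
    s2 <- s2 + sub[v]^2 * m_b
    sub[p] <- sub[p] + sub[v]
  }
  s2 / nsamp^2
}

#' ASD (average squared distance) TMRCA
#'
#' `ASD = (1/(n L)) sum_i sum_l (a_il - f_l)^2` grows linearly in time at
#' rate `mu` per locus under the stepwise model (the squared displacement of
#' a +-1 random walk equals its number of steps in expectation), so
#' `age = ASD / mu * g`. Squared differences weight multi-step divergence
#' fully, so ASD (unlike rho) is not deflated by mutations that cancel within
#' a lineage's net displacement.
#'
#' @inheritParams rho_age
#' @return A `ystr_age` object with `asd`, `age_asd_years`, `n`.
#' @export
asd_age <- function(haplotypes, founder, params = mutation_model()) {
  if (inherits(founder, "ystr_modal")) founder <- founder$haplotype
  n <- length(haplotypes)
  if (n < 1) ystr_abort("need at least one haplotype",
                        "ystr_validation_error")
  if (!identical(colnames(founder$alleles), colnames(haplotypes$alleles))) {
    ystr_abort("founder locus set does not match the haplotypes",
               "ystr_locus_error")
  }
  f <- founder$alleles[1, ]
  sq <- sweep(haplotypes$alleles, 2, f)^2
  drop19 <- haplotypes$dys19_dup | founder$dys19_dup[1]
  Lfull <- ncol(sq)
  per_sample <- ifelse(drop19,
                       (rowSums(sq) - sq[, "DYS19"]) / (Lfull - 1),
                       rowSums(sq) / Lfull)
  asd <- mean(per_sample)
  structure(list(
    asd = asd, age_asd_years = asd / params$mu * params$g, n = n,
    mu = params$mu, generation_years = params$g, n_loci = params$L
  ), class = "ystr_age")
}

#' @export
print.ystr_age <- function(x, ...) {
  if (!is.null(x$rho)) {
    cat(sprintf("<ystr_age (rho): rho = %.3f, age = %.0f +/- %.0f years, n = %d>\n",
                x$rho, x$age_rho_years, x$sd_rho_years, x$n))
  }
  if (!is.null(x$asd)) {
    cat(sprintf("<ystr_age (ASD): asd = %.4f, age = %.0f years, n = %d>\n",
                x$asd, x$age_asd_years, x$n))
  }
  invisible(x)
}
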