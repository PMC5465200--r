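#' Reference founder haplotype
#'
#' The most frequent Transoxianan modal haplotype (haplogroup C2b1a2-M48),
#' used as the default simulation founder.
#'
#' @return A length-1 [str_haplotypes()] object.
#' @export
default_founder <- function() {
  str_haplotypes(
    c(DYS389I = 14, DYS389b = 17, DYS390 = 25, DYS456 = 15, DYS19 = 16,
      DYS458 = 17, DYS437 = 14, DYS438 = 10, DYS448 = 20, GATA_H4 = 10,
      DYS391 = 10, DYS392 = 11, DYS393 = 13, DYS439 = 11, DYS635 = 23),
    haplogroup = "C2b1a2-M48", id = "FOUNDER")
}

#' Simulate a clan expansion from a founder haplotype
#'
#' Generates `n_samples` present-day Y-STR haplotypes descending from a
#' single founder under the symmetric single-step mutation model (each
#' mutation changes one locus by +-1 repeat; multi-step mutations are not
#' modelled). Two genealogies are available:
#' \describe{
#'   \item{star}{every sampled lineage is an independent branch of length
#'     `depth_generations`; mutation counts per locus are
#'     Poisson(`mu * depth`), so non-integer depths are supported.}
#'   \item{galton_watson}{a discrete branching process over integer
#'     generations with Poisson(`offspring_mean`) offspring per lineage,
#'     conditioned on survival to the final generation with at least
#'     `n_samples` lineages (resimulated up to `max_retries` times);
#'     per-generation, per-locus mutation probability `mu`.}
#' }
#' Repeat counts have a floor of 5: a downward step at the floor is applied
#' upward instead (non-physical alleles would otherwise arise; at the depths
#' of interest this is vanishingly rare).
#'
#' @param n_samples Number of sampled present-day lineages.
#' @param depth_generations Time to the founder in generations (> 0;
#'   integer for `galton_watson`).
#' @param genealogy `"star"` or `"galton_watson"`.
#' @param offspring_mean Mean offspring per lineage (galton_watson only).
#' @param params A [mutation_model()].
#' @param founder Founder haplotype (default [default_founder()]).
#' @param haplogroup_label Label attached to all simulated haplotypes.
#' @param population Population code attached to the samples.
#' @param seed Integer seed (mandatory; RNG state restored afterwards).
#' @param max_retries Resimulation attempts for galton_watson survival.
#' @return List with `haplotypes` (a [str_haplotypes()]) and `truth`
#'   (`true_tmrca_years`, parent pointers, per-branch mutation records,
#'   founder).
#' @export
simulate_clan <- function(n_samples, depth_generations,
                          genealogy = c("star", "galton_watson"),
                          offspring_mean = 1.5,
                          params = mutation_model(),
                          founder = default_founder(),
                          haplogroup_label = founder$haplogroup[1],
                          population = "SIM1",
                          seed, max_retries = 100) {
  genealogy <- match.arg(genealogy)
  if (missing(seed)) ystr_abort("seed is mandatory", "ystr_validation_error")
  if (n_samples < 1 || depth_generations <= 0) {
    ystr_abort("need n_samples >= 1 and depth_generations > 0",
               "ystr_validation_error")
  }
  with_seed(seed, {
    if (genealogy == "star") {
      sim_star(n_samples, depth_generations, params, founder,
               haplogroup_label, population)
    } else {
      if (depth_generations != round(depth_generations)) {
        ystr_abort("galton_watson requires integer depth_generations",
                   "ystr_validation_error")
      }
      sim_gw(n_samples, as.integer(depth_generations), offspring_mean,
             params, founder, haplogroup_label, population, max_retries)
    }
  })
}

# apply k single +-1 steps to one allele value with floor at ALLELE_MIN;
# returns list(value, steps applied)
apply_steps <- function(value, k) {
  steps <- integer(k)
  for (s in seq_len(k)) {
    st <- if (runif(1) < 0.5) -1L else 1L
    if (value + st < ALLELE_MIN) st <- 1L
    value <- value + st
    steps[s] <- st
  }
  list(value = value, steps = steps)
}

sim_star <- function(n, depth, params, founder, hg, pop) {
  L <- length(YSTR_15_LOCI)
  f <- founder$alleles[1, ]
  K <- matrix(rpois(n * L, params$mu * depth), n, L)
  alleles <- matrix(rep(f, each = n), n, L,
                    dimnames = list(NULL, YSTR_15_LOCI))
  mut <- vector("list", n)
  hit <- which(K > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; l <- hit[r, 2]
      res <- apply_steps(alleles[i, l], K[i, l])
      alleles[i, l] <- res$value
      prev <- mut[[i]]
      mut[[i]] <- list(
        locus = c(prev$locus, rep(YSTR_15_LOCI[l], K[i, l])),
        step = c(prev$step, res$steps))
    }
  }
  haps <- str_haplotypes(alleles, haplogroup = hg,
                         id = sprintf("SIM%04d", seq_len(n)),
                         population = pop)
  truth <- list(true_tmrca_years = depth * params$g,
                genealogy = "star",
                parent = rep(0L, n), # every branch hangs off the founder
                branch_mutations = mut,
                n_mutations = sum(K),
                founder = founder)
  list(haplotypes = haps, truth = truth)
}

sim_gw <- function(n, depth, lambda, params, founder, hg, pop, max_retries) {
  L <- length(YSTR_15_LOCI)
  for (try in seq_len(max_retries)) {
    parent <- integer(0)   # index into node list; 0 = founder
    gen_of <- integer(0)
    alleles <- matrix(integer(0), 0, L)
    mut <- list()
    cur_nodes <- 0L        # founder
    cur_alleles <- matrix(founder$alleles[1, ], 1, L)
    ok <- TRUE
    for (g in seq_len(depth)) {
      n_off <- rpois(length(cur_nodes), lambda)
      if (sum(n_off) == 0) { ok <- FALSE; break }
      if (sum(n_off) > 1e5) {
        ystr_abort("galton_watson population exceeded 1e5 lineages",
                   "ystr_sim_error")
      }
      idx_parent <- rep(seq_along(cur_nodes), n_off)
      new_alleles <- cur_alleles[idx_parent, , drop = FALSE]
      new_mut <- vector("list", nrow(new_alleles))
      hits <- which(matrix(runif(nrow(new_alleles) * L), ncol = L) <
                      params$mu, arr.ind = TRUE)
      if (nrow(hits)) {
        for (r in seq_len(nrow(hits))) {
          i <- hits[r, 1]; l <- hits[r, 2]
          res <- apply_steps(new_alleles[i, l], 1L)
          new_alleles[i, l] <- res$value
          prev <- new_mut[[i]]
          new_mut[[i]] <- list(locus = c(prev$locus, YSTR_15_LOCI[l]),
                               step = c(prev$step, res$steps))
        }
      }
      base <- length(parent)
      parent <- c(parent, cur_nodes[idx_parent])
      gen_of <- c(gen_of, rep(g, nrow(new_alleles)))
      alleles <- rbind(alleles, new_alleles)
      mut <- c(mut, new_mut)
      cur_nodes <- base + seq_len(nrow(new_alleles))
      cur_alleles <- new_alleles
    }
    if (ok && length(cur_nodes) >= n) {
      tips <- sort(sample(cur_nodes, n))
      haps <- str_haplotypes(alleles[tips, , drop = FALSE],
                             haplogroup = hg,
                             id = sprintf("SIM%04d", seq_len(n)),
                             population = pop)
      truth <- list(true_tmrca_years = depth * params$g,
                    genealogy = "galton_watson",
                    parent = parent, sampled_nodes = tips,
                    branch_mutations = mut,
                    founder = founder, retries = try - 1L)
      return(list(haplotypes = haps, truth = truth))
    }
  }
  ystr_abort(sprintf(
    "galton_watson genealogy died out in all %d attempts", max_retries),
    "ystr_sim_error")
}

#' Simulate grouped populations with divergent haplogroup frequencies
#'
#' Group mean frequencies are drawn from a Dirichlet around
#' `base_frequencies` with total mass `concentration` (small values =>
#' strongly divergent groups; values >= 1e6 are treated as the exact-base
#' null limit). Population frequencies are drawn from a Dirichlet around
#' their group mean with mass `pop_concentration`, and individuals are
#' multinomial. Coordinates are uniform in `coordinate_box`; with
#' `spatial_segregation` each group occupies its own longitude slice, which
#' induces a genuine genetics-geography correlation (Mantel signal).
#'
#' @param n_groups,pops_per_group,samples_per_pop Design sizes.
#' @param base_frequencies Named haplogroup frequency vector (sums to 1).
#' @param concentration Dirichlet mass for group divergence (> 0).
#' @param pop_concentration Dirichlet mass for within-group population
#'   scatter (default 100: moderate, realistic drift between neighbouring
#'   populations).
#' @param coordinate_box List with `lat` and `lon` ranges (default spans
#'   the Amu Darya / Syr Darya region).
#' @param spatial_segregation Logical; geographically separate the groups.
#' @param seed Integer seed (mandatory).
#' @return List with `records` (data frame: sample_id, population,
#'   haplogroup), `meta` (population coordinates + `group`), `scheme`
#'   (a [grouping_scheme()]), `truth` (true group/population frequencies).
#' @export
simulate_populations <- function(n_groups = 2, pops_per_group = 3,
                                 samples_per_pop = 50,
                                 base_frequencies = c(
                                   "C2-M217" = 0.31, "R1a1a-M198" = 0.16,
                                   "Q-M242" = 0.13, "J2-M172" = 0.10,
                                   "O2-M122" = 0.08, "other" = 0.22),
                                 concentration = 20,
                                 pop_concentration = 100,
                                 coordinate_box = list(lat = c(37, 46),
                                                       lon = c(55, 70)),
                                 spatial_segregation = FALSE,
                                 seed) {
  if (missing(seed)) ystr_abort("seed is mandatory", "ystr_validation_error")
  if (abs(sum(base_frequencies) - 1) > 1e-9 || concentration <= 0) {
    ystr_abort("base frequencies must sum to 1 and concentration be > 0",
               "ystr_validation_error")
  }
  K <- length(base_frequencies)
  hg_names <- names(base_frequencies) %||% paste0("HG", seq_len(K))
  with_seed(seed, {
    group_freq <- t(vapply(seq_len(n_groups), function(g) {
      if (concentration >= 1e6) as.numeric(base_frequencies)
      else rdirichlet1(concentration * base_frequencies)
    }, numeric(K)))
    records <- NULL
    meta <- NULL
    assignment <- character(0)
    pop_freq <- matrix(NA_real_, n_groups * pops_per_group, K)
    lon_rng <- coordinate_box$lon
    lon_slices <- seq(lon_rng[1], lon_rng[2], length.out = n_groups + 1)
    pi_ <- 0L
    for (g in seq_len(n_groups)) {
      for (p in seq_len(pops_per_group)) {
        pi_ <- pi_ + 1L
        code <- sprintf("G%dP%d", g, p)
        fr <- rdirichlet1(pop_concentration * group_freq[g, ])
        pop_freq[pi_, ] <- fr
        cnt <- as.integer(rmultinom(1, samples_per_pop, fr))
        hgs <- rep(hg_names, cnt)
        records <- rbind(records, data.frame(
          sample_id = sprintf("%s_S%03d", code, seq_len(samples_per_pop)),
          population = code,
          haplogroup = hgs[sample.int(samples_per_pop)],
          stringsAsFactors = FALSE))
        lr <- if (spatial_segregation) lon_slices[g + 0:1] else lon_rng
        meta <- rbind(meta, data.frame(
          population = code, group = sprintf("group%d", g),
          latitude = runif(1, coordinate_box$lat[1], coordinate_box$lat[2]),
          longitude = runif(1, lr[1], lr[2]),
          stringsAsFactors = FALSE))
        assignment[code] <- sprintf("group%d", g)
      }
    }
    class(meta) <- c("ystr_meta", "data.frame")
    list(records = records, meta = meta,
         scheme = grouping_scheme("simulated_groups", assignment),
         truth = list(group_frequencies = group_freq,
                      population_frequencies = pop_freq,
                      haplogroups = hg_names,
                      base_frequencies = base_frequencies))
  })
}

#' Replay recorded mutations from the founder
#'
#' Applies each sampled branch's recorded mutation steps to the founder
#' profile; by construction this must reproduce the emitted haplotypes
#' exactly (the simulator's core invariant).
#'
#' @param truth A `truth` record from [simulate_clan()].
#' @param n Number of sampled haplotypes to reconstruct.
#' @return Integer allele matrix, one row per sample.
#' @export
replay_truth <- function(truth, n) {
  f <- truth$founder$alleles[1, ]
  if (truth$genealogy == "star") {
    out <- matrix(rep(f, each = n), n, length(f),
                  dimnames = list(NULL, names(f)))
    for (i in seq_len(n)) {
      m <- truth$branch_mutations[[i]]
      if (!is.null(m)) {
        for (r in seq_along(m$step)) {
          out[i, m$locus[r]] <- out[i, m$locus[r]] + m$step[r]
        }
      }
    }
    return(out)
  }
  # galton_watson: accumulate along the parent chain of each sampled node
  out <- matrix(NA_integer_, length(truth$sampled_nodes), length(f),
                dimnames = list(NULL, names(f)))
  for (s in seq_along(truth$sampled_nodes)) {
    chain <- integer(0)
    v <- truth$sampled_nodes[s]
    while (v != 0) { chain <- c(v, chain); v <- truth$parent[v] }
    al <- f
    for (v in chain) {
      m <- truth$branch_mutations[[v]]
      if (!is.null(m)) {
        for (r in seq_along(m$step)) al[m$locus[r]] <- al[m$locus[r]] + m$step[r]
      }
    }
    out[s, ] <- al
  }
  out
}
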