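# independent oracles: deliberately brute-force implementations that share no
# code with the package internals they check

# AMOVA variance components computed directly from the full 0/1 distance
# matrix via explicit sums of squared distances (Excoffier decomposition)
oracle_amova <- function(haplogroup, population, group_of_pop) {
  N <- length(haplogroup)
  D2 <- outer(haplogroup, haplogroup, FUN = function(a, b) as.numeric(a != b))
  pops <- sort(unique(population))
  grp <- group_of_pop[pops]
  groups <- sort(unique(grp))
  ssd_set <- function(idx) sum(D2[idx, idx]) / (2 * length(idx))

  ssd_total <- ssd_set(seq_len(N))
  ssd_wp <- sum(vapply(pops, function(p) ssd_set(which(population == p)),
                       numeric(1)))
  ssd_group <- vapply(groups, function(g) {
    ssd_set(which(population %in% pops[grp == g]))
  }, numeric(1))
  ssd_ap <- sum(ssd_group) - ssd_wp
  ssd_ag <- ssd_total - sum(ssd_group)

  P <- length(pops); G <- length(groups)
  n_p <- vapply(pops, function(p) sum(population == p), numeric(1))
  n_g <- vapply(groups, function(g) sum(population %in% pops[grp == g]),
                numeric(1))
  df_ag <- G - 1; df_ap <- P - G; df_wp <- N - P
  sum_npg2_over_ng <- sum(vapply(groups, function(g) {
    sum(n_p[grp == g]^2) / n_g[groups == g]
  }, numeric(1)))
  s2c <- ssd_wp / df_wp
  if (df_ap > 0) {
    n1 <- (N - sum_npg2_over_ng) / df_ap
    s2b <- (ssd_ap / df_ap - s2c) / n1
  } else s2b <- 0
  n2 <- (sum_npg2_over_ng - sum(n_p^2) / N) / df_ag
  n3 <- (N - sum(n_g^2) / N) / df_ag
  s2a <- (ssd_ag / df_ag - s2c - n2 * s2b) / n3
  c(among_groups = s2a, among_pops = s2b, within = s2c)
}

# exact Mantel p by full enumeration of all n! label permutations
oracle_mantel_exact <- function(m1, m2) {
  n <- nrow(m1)
  ut <- upper.tri(m1)
  r_obs <- cor(m1[ut], m2[ut])
  perms <- perm_all(n)
  rs <- apply(perms, 1, function(idx) cor(m1[ut], m2[idx, idx][ut]))
  list(r = r_obs, p = mean(abs(rs) >= abs(r_obs) - 1e-12))
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- perm_all(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# brute-force Steiner cost: minimal MST weight over the observed profiles
# plus up to `max_extra` candidate points drawn from the per-locus allele
# ranges (exhaustive grid; only feasible for tiny inputs)
oracle_steiner_cost <- function(profiles, max_extra = 2) {
  mst_w <- function(P) {
    D <- as.matrix(dist(P, method = "manhattan"))
    n <- nrow(D)
    in_tree <- c(TRUE, rep(FALSE, n - 1))
    total <- 0
    while (!all(in_tree)) {
      cand <- which(!in_tree)
      best <- min(vapply(cand, function(j) min(D[j, in_tree]), numeric(1)))
      j <- cand[which.min(vapply(cand, function(j) min(D[j, in_tree]),
                                 numeric(1)))]
      total <- total + best
      in_tree[j] <- TRUE
    }
    total
  }
  ranges <- lapply(seq_len(ncol(profiles)), function(j) {
    seq(min(profiles[, j]), max(profiles[, j]))
  })
  grid <- as.matrix(expand.grid(ranges))
  colnames(grid) <- colnames(profiles)
  have <- apply(profiles, 1, paste, collapse = "-")
  grid <- grid[!apply(grid, 1, paste, collapse = "-") %in% have, ,
               drop = FALSE]
  best <- mst_w(profiles)
  for (k in seq_len(min(max_extra, nrow(grid)))) {
    combos <- utils::combn(nrow(grid), k)
    for (q in seq_len(ncol(combos))) {
      w <- mst_w(rbind(profiles, grid[combos[, q], , drop = FALSE]))
      if (w < best) best <- w
    }
  }
  best
}

# independent stress minimiser: direct numerical optimisation of raw stress
# from the classical-scaling start
oracle_mds_stress <- function(delta, k) {
  n <- nrow(delta)
  X0 <- cmdscale(delta, k = k)
  obj <- function(v) {
    X <- matrix(v, n, k)
    d <- as.matrix(dist(X))
    sum((delta - d)[upper.tri(delta)]^2)
  }
  fit <- optim(as.vector(X0), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-15))
  d <- as.matrix(dist(matrix(fit$par, n, k)))
  sqrt(sum((d - delta)[upper.tri(delta)]^2) /
         sum(delta[upper.tri(delta)]^2))
}
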