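params <- mutation_model() # mu = 0.0021, g = 30, L = 15
year_per_step <- 30 / (15 * 0.0021) # 952.38 years per mean mutational step

test_that("identical haplotypes date to age zero", {
  h <- reps(hap(), 5)
  ra <- rho_age(h, hap(), params = params)
  aa <- asd_age(h, hap(), params = params)
  expect_equal(ra$rho, 0)
  expect_equal(ra$age_rho_years, 0)
  expect_equal(aa$age_asd_years, 0)
})

test_that("a one-step star matches the closed form", {
  n <- 9
  loci <- names(base_profile())[1:9]
  h <- do.call(c, lapply(seq_len(n), function(i) {
    args <- list(1); names(args) <- loci[i]
    args$id <- paste0("t", i)
    do.call(hap, args)
  }))
  ra <- rho_age(h, hap(), params = params)
  expect_equal(ra$rho, 1)
  expect_equal(ra$sigma_rho, 1 / sqrt(n))
  expect_equal(ra$age_rho_years, year_per_step, tolerance = 1e-9) # 952.4
  aa <- asd_age(h, hap(), params = params)
  expect_equal(aa$asd, 1 / 15)
  expect_equal(aa$age_asd_years, year_per_step, tolerance = 1e-9)
})

test_that("rho converts to years as rho / (L mu) * g", {
  # rho = 0.63 corresponds to 20 generations = 600 years
  expect_equal(0.63 / (15 * 0.0021) * 30, 600)
  h <- c(reps(hap(), 37), do.call(c, lapply(1:63, function(i)
    hap(DYS390 = 1, id = i)))) # 63/100 one step away
  ra <- rho_age(h, hap(), params = params)
  expect_equal(ra$rho, 0.63)
  expect_equal(ra$age_rho_years, 600, tolerance = 1e-9)
})

test_that("single-sample multi-step ASD matches hand arithmetic", {
  h1 <- hap(DYS390 = 2)
  aa <- asd_age(h1, hap(), params = params)
  expect_equal(aa$asd, 4 / 15)
  expect_equal(aa$age_asd_years, (4 / 15) / 0.0021 * 30, tolerance = 1e-9)
  # 3809.5 years, vs the rho age of the same input:
  ra <- rho_age(h1, hap(), params = params)
  expect_equal(ra$age_rho_years, 2 * year_per_step, tolerance = 1e-9)
  expect_gt(aa$age_asd_years, ra$age_rho_years) # squares dominate
})

test_that("ASD age is at least the rho age on multi-step inputs", {
  h <- c(hap(DYS390 = 3), hap(DYS439 = -2), hap(DYS19 = 1))
  ra <- rho_age(h, hap(), params = params)
  aa <- asd_age(h, hap(), params = params)
  expect_gte(aa$age_asd_years, ra$age_rho_years)
})

test_that("ages scale linearly in g and inversely in mu", {
  h <- c(hap(DYS390 = 1), hap(DYS439 = 2))
  base_ra <- rho_age(h, hap(), params = mutation_model())$age_rho_years
  base_aa <- asd_age(h, hap(), params = mutation_model())$age_asd_years
  for (f in c(0.5, 2, 3)) {
    expect_equal(rho_age(h, hap(),
                         params = mutation_model(g = 30 * f))$age_rho_years,
                 base_ra * f, tolerance = 1e-12)
    expect_equal(rho_age(h, hap(),
                         params = mutation_model(mu = 0.0021 * f))$age_rho_years,
                 base_ra / f, tolerance = 1e-12)
    expect_equal(asd_age(h, hap(),
                         params = mutation_model(mu = 0.0021 * f))$age_asd_years,
                 base_aa / f, tolerance = 1e-12)
  }
})

test_that("network-based sigma reduces to the star formula on a star", {
  h <- c(hap(DYS390 = 1, id = "a", pop = "P"),
         hap(DYS439 = 1, id = "b", pop = "P"),
         hap(DYS19 = 1, id = "c", pop = "P"),
         hap(id = "d", pop = "P"))
  net <- build_network(c(h, reps(hap(), 2, pop = "P")))
  ra_star <- rho_age(c(h, reps(hap(), 2)), hap())
  ra_net <- rho_age(c(h, reps(hap(), 2)), hap(), net = net)
  expect_equal(ra_net$rho, ra_star$rho)
  # on a star each sampled mutation sits on its own branch: sigma^2 = rho/n
  expect_equal(ra_net$sigma_rho, ra_star$sigma_rho, tolerance = 1e-9)
  expect_equal(ra_net$sigma_method, "network_branches")
})

test_that("shared internal branches increase sigma over the star formula", {
  # 4 samples hanging off one internal node two steps from the founder:
  # all root paths share the internal branch, inflating the variance
  inner <- hap(DYS390 = 2)
  tips <- c(hap(DYS390 = 2, DYS439 = 1, id = "t1", pop = "P"),
            hap(DYS390 = 2, DYS19 = 1, id = "t2", pop = "P"),
            hap(DYS390 = 2, DYS392 = 1, id = "t3", pop = "P"),
            hap(DYS390 = 2, DYS456 = 1, id = "t4", pop = "P"))
  all_h <- c(reps(hap(), 2, pop = "P"),
             str_haplotypes(inner$alleles, inner$haplogroup[1],
                            id = "inner", population = "P"), tips)
  net <- build_network(all_h)
  ra_net <- rho_age(all_h, hap(), net = net)
  ra_star <- rho_age(all_h, hap())
  expect_gt(ra_net$sigma_rho, ra_star$sigma_rho)
})

test_that("founder locus mismatches are rejected", {
  h <- reps(hap(), 2)
  bad <- hap()
  colnames(bad$alleles)[1] <- "WRONG"
  expect_error(rho_age(h, bad), class = "ystr_locus_error")
  expect_error(asd_age(h, bad), class = "ystr_locus_error")
  expect_error(mutation_model(mu = 0), class = "ystr_validation_error")
})
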