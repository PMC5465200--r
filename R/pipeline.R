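#' SNP calls consistent with a haplogroup label
#'
#' Inverse of [assign_haplogroup()] for writing simulated sample tables:
#' the node's marker and all its typed ancestors are set derived; for
#' paragroup labels (`X*-M(xY)`) the excluded child markers are set
#' ancestral. Other markers stay untyped.
#'
#' @param label Haplogroup label present in `tree` (plain or paragroup form),
#'   or `"unresolved"`.
#' @param tree A [marker_tree()].
#' @return Named character vector over typed markers (`"D"`/`"A"`).
#' @export
snp_calls_for <- function(label, tree) {
  if (label == "unresolved") {
    return(setNames("A", tree$marker[tree$parent == "Y"][1]))
  }
  excl <- character(0)
  if (grepl("\\*-", label)) {
    marker <- sub("^.*\\*-([^(]+)\\(.*$", "\\1", label)
    excl <- strsplit(sub("^.*\\(x([^)]*)\\)$", "\\1", label), ",")[[1]]
    i <- match(marker, tree$marker)
  } else {
    i <- match(label, tree$label)
  }
  if (is.na(i)) {
    ystr_abort(sprintf("label '%s' not in the marker tree", label),
               "ystr_validation_error")
  }
  calls <- setNames("D", tree$marker[i])
  p <- tree$parent[i]
  while (p != "Y") {
    j <- match(p, tree$label)
    calls[tree$marker[j]] <- "D"
    p <- tree$parent[j]
  }
  for (m in excl) calls[m] <- "A"
  calls
}

#' Write simulated haplotypes as a raw sample table
#'
#' Emits the TSV dialect that [read_sample_table()] reads: raw 17-locus STR
#' columns reconstructed from the 15-locus profile (`DYS389II = DYS389I +
#' DYS389b`; constant placeholder DYS385a/b; `DYS19_2` populated for
#' duplicated-DYS19 haplotypes) plus SNP columns consistent with each
#' haplotype's haplogroup label.
#'
#' @param haplotypes A [str_haplotypes()] set.
#' @param path Output TSV path.
#' @param tree A [marker_tree()] for SNP reconstruction.
#' @return Invisibly, `path`.
#' @export
write_sample_table <- function(haplotypes, path, tree = marker_tree()) {
  a <- haplotypes$alleles
  df <- data.frame(sample_id = haplotypes$id,
                   population = haplotypes$population,
                   clan = NA_character_,
                   stringsAsFactors = FALSE)
  labs <- unique(haplotypes$haplogroup)
  callset <- lapply(labs, snp_calls_for, tree = tree)
  markers <- sort(unique(unlist(lapply(callset, names))))
  for (m in markers) {
    df[[m]] <- vapply(haplotypes$haplogroup, function(h) {
      cs <- callset[[match(h, labs)]]
      if (m %in% names(cs)) cs[[m]] else NA_character_
    }, character(1))
  }
  df$DYS389I <- a[, "DYS389I"]
  df$DYS389II <- a[, "DYS389I"] + a[, "DYS389b"]
  for (loc in setdiff(YSTR_15_LOCI, c("DYS389I", "DYS389b"))) {
    df[[loc]] <- a[, loc]
  }
  df$DYS19_2 <- ifelse(haplotypes$dys19_dup, a[, "DYS19"], NA_integer_)
  df$DYS385a <- 12L
  df$DYS385b <- 14L
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects inputs, thresholds, model parameters, permutation counts and the
#' single global seed. Defaults follow the analysis conventions used
#' throughout the package: modal threshold 10, related radius 4, enrichment
#' 0.5, distance cap = related radius, mu = 0.0021, g = 30, L = 15.
#'
#' @param samples Path to the sample table TSV.
#' @param meta Path to the population metadata TSV.
#' @param outdir Output directory (created if needed).
#' @param schemes Character vector of metadata columns to use as AMOVA
#'   grouping schemes.
#' @param modal_threshold,related_radius,enrichment,distance_cap Analysis
#'   thresholds.
#' @param mu,generation_years,n_loci Mutation model parameters.
#' @param n_perm Permutation count for AMOVA and Mantel.
#' @param seed Global seed; per-stage seeds are derived as
#'   `seed + 101 * stage_index`, so adding a stage never perturbs earlier
#'   stages' randomness.
#' @param json Optionally, a path to a JSON file holding any of the above
#'   fields (explicit arguments win).
#' @return A `ystr_config` list.
#' @export
pipeline_config <- function(samples = NULL, meta = NULL, outdir = "ystr_out",
                            schemes = "group",
                            modal_threshold = 10, related_radius = 4,
                            enrichment = 0.5, distance_cap = NULL,
                            mu = 2.1e-3, generation_years = 30, n_loci = 15,
                            n_perm = 9999, seed = 1, json = NULL) {
  cfg <- list(samples = samples, meta = meta, outdir = outdir,
              schemes = schemes, modal_threshold = modal_threshold,
              related_radius = related_radius, enrichment = enrichment,
              distance_cap = distance_cap %||% related_radius,
              mu = mu, generation_years = generation_years, n_loci = n_loci,
              n_perm = n_perm, seed = seed)
  if (!is.null(json)) {
    file_cfg <- jsonlite::fromJSON(json, simplifyVector = TRUE)
    supplied <- names(as.list(match.call()))
    for (k in names(file_cfg)) {
      if (!k %in% supplied && k %in% names(cfg)) cfg[[k]] <- file_cfg[[k]]
    }
  }
  structure(cfg, class = "ystr_config")
}

stage_seed <- function(cfg, idx) as.integer(cfg$seed + 101L * idx)

#' Run the full analysis pipeline
#'
#' Executes load, haplogroup assignment, frequency tables, Nei and
#' geographic distances, MDS, PCA, AMOVA per scheme, Mantel, modal-haplotype
#' detection, related-haplotype search, median-joining networks, descent
#' clusters and rho/ASD dating, writing per-stage outputs under
#' `cfg$outdir` and a manifest JSON with an MD5 hash per file. The manifest
#' is a pure function of (inputs, config, seed): identical runs give
#' identical hashes. On stage failure a `<stage>.partial` marker is left in
#' the output directory and a classed error naming the stage is raised.
#'
#' @param cfg A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `file.path(cfg$outdir, "manifest.json")`).
#' @export
run_pipeline <- function(cfg) {
  if (is.null(cfg$samples) || !file.exists(cfg$samples)) {
    ystr_abort(sprintf("input sample table missing: %s",
                       cfg$samples %||% "<unset>"), "ystr_io_error")
  }
  if (is.null(cfg$meta) || !file.exists(cfg$meta)) {
    ystr_abort(sprintf("input metadata missing: %s", cfg$meta %||% "<unset>"),
               "ystr_io_error")
  }
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  params <- mutation_model(cfg$mu, cfg$generation_years, cfg$n_loci)
  files <- character(0)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, msg)
    message("[ystr] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      file.create(file.path(cfg$outdir, paste0(name, ".partial")))
      ystr_abort(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)), "ystr_stage_error")
    })
  }
  out <- function(fn) {
    files <<- c(files, fn)
    file.path(cfg$outdir, fn)
  }

  tree <- marker_tree()
  samples <- stage("load", {
    s <- read_sample_table(cfg$samples)
    note("load: %d samples from %s", nrow(s), basename(cfg$samples))
    s
  })
  meta <- stage("load", read_population_meta(cfg$meta))

  samples <- stage("assign", {
    if (!"haplogroup" %in% names(samples)) {
      typed <- intersect(YSNP_MARKERS, names(samples))
      samples$haplogroup <- vapply(seq_len(nrow(samples)), function(i) {
        calls <- unlist(samples[i, typed, drop = FALSE])
        assign_haplogroup(setNames(as.character(calls), typed), tree)
      }, character(1))
    }
    note("assign: %d haplogroups", length(unique(samples$haplogroup)))
    samples
  })

  ft <- stage("freqs", {
    ft <- frequency_table(samples, by = "population")
    write_results(ft, out("haplogroup_frequencies.tsv"), "tsv")
    ft
  })

  dn <- stage("distances", {
    dn <- nei_distance_matrix(ft)
    write_results(dn, out("nei_distances.tsv"), "tsv")
    dn
  })
  dgeo <- stage("distances", {
    dg <- geographic_distance(meta[meta$population %in% ft$populations, ])
    write_results(dg, out("geographic_distances.tsv"), "tsv")
    dg
  })

  stage("ordination", {
    if (all(is.finite(dn$d)) && nrow(dn$d) > 3) {
      m <- mds(dn, k = 2)
      write_results(m, out("mds_coordinates.tsv"), "tsv")
      note("mds: stress-1 = %.4f", m$stress)
    } else {
      note("mds: skipped (infinite distances or too few populations)")
    }
    p <- pca(ft, k = min(3, nrow(ft$p) - 1))
    write_results(p, out("pca_coordinates.tsv"), "tsv")
  })

  stage("amova", {
    for (si in seq_along(cfg$schemes)) {
      sc <- cfg$schemes[si]
      if (!sc %in% names(meta)) {
        ystr_abort(sprintf("scheme column '%s' absent from metadata", sc),
                   "ystr_schema_error")
      }
      scheme <- grouping_scheme(sc, setNames(as.character(meta[[sc]]),
                                             meta$population))
      res <- amova(samples, scheme, n_perm = cfg$n_perm,
                   seed = stage_seed(cfg, 10L + si))
      write_results(res, out(sprintf("amova_%s.json", sc)), "json")
      note("amova[%s]: among-groups %.2f%% (p = %.4g)", sc,
           res$pct_among_groups, res$p_values["phi_ct"])
    }
  })

  stage("mantel", {
    common <- intersect(rownames(dn$d), rownames(dgeo$d))
    ut <- upper.tri(dn$d[common, common])
    if (length(common) < 3 || any(!is.finite(dn$d[common, common]))) {
      note("mantel: skipped (infinite Nei distances or too few populations)")
    } else if (stats::sd(dn$d[common, common][ut]) == 0 ||
               stats::sd(dgeo$d[common, common][ut]) == 0) {
      note("mantel: skipped (degenerate distance triangle)")
    } else {
      mt <- mantel(dn$d[common, common], dgeo$d[common, common],
                   n_perm = cfg$n_perm, seed = stage_seed(cfg, 20L))
      write_results(mt, out("mantel.json"), "json")
      note("mantel: r = %.4f, p = %.4g", mt$r, mt$p_value)
    }
  })

  haps <- stage("derive", {
    h <- derive_haplotypes(samples, samples$haplogroup)
    note("derive: %d haplotypes kept, %d excluded for missing loci",
         length(h), length(attr(h, "excluded")))
    h
  })

  cluster_report <- stage("clusters", {
    modals <- find_modal_haplotypes(haps, threshold = cfg$modal_threshold)
    note("modal: %d modal haplotype(s) above threshold %d",
         length(modals), cfg$modal_threshold)
    report <- list()
    for (mi in seq_along(modals)) {
      mo <- modals[[mi]]
      rel <- related_search(mo, haps, radius = cfg$related_radius)
      entry <- list(modal = paste(mo$haplotype$alleles[1, ], collapse = "-"),
                    haplogroup = mo$haplotype$haplogroup[1],
                    n_modal = mo$count, n_related = rel$n)
      keys <- profile_key(rel$members)
      if (length(unique(keys)) >= 2) {
        net <- build_network(rel$members)
        write_results(net, out(sprintf("network_modal%d.graphml", mi)),
                      "graphml")
        pops <- table(rel$members$population)
        seed_pop <- names(pops)[order(-pops, names(pops))][1]
        cl <- delineate_cluster(net, seed_pop, mo,
                                enrichment_threshold = cfg$enrichment,
                                distance_cap = cfg$distance_cap,
                                name = sprintf("cluster%d", mi))
        members <- rel$members[keys %in%
                                 apply(net$profiles[cl$members, ,
                                                    drop = FALSE],
                                       1, paste, collapse = "-")]
        entry$seed_population <- seed_pop
        entry$n_cluster <- cl$n_samples
        entry$enrichment <- cl$enrichment
        if (length(members)) {
          ra <- rho_age(members, mo, net = net, params = params)
          aa <- asd_age(members, mo, params = params)
          entry$age_rho_years <- ra$age_rho_years
          entry$sd_rho_years <- ra$sd_rho_years
          entry$age_asd_years <- aa$age_asd_years
        }
      }
      report[[sprintf("modal%d", mi)]] <- entry
    }
    jsonlite::write_json(report, out("cluster_report.json"),
                         auto_unbox = TRUE, digits = 6, pretty = TRUE)
    report
  })

  manifest <- list(
    package = "ystr",
    config = unclass(cfg),
    log = log,
    files = lapply(setNames(sort(files), sort(files)), function(fn) {
      list(md5 = unname(tools::md5sum(file.path(cfg$outdir, fn))))
    })
  )
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(manifest)
}
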