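#' Published descent-cluster reference features
#'
#' Summary features of the seven primary Transoxianan descent clusters
#' (alpha, beta, sigma, gamma, mu, lambda, delta): founder (modal or
#' cluster-specific) 15-locus haplotype, haplogroup, carrier counts
#' (`n_modal` = identical carriers, `n_related` = haplotypes within 4 steps,
#' `n_cluster` = haplotypes attributed to the clade) and published rho/ASD
#' TMRCA estimates in years. These printed values parameterise the
#' estimator-recovery experiments: simulating a cluster's size at the depth
#' implied by its rho age (`age / 30` generations) should recover the age.
#'
#' @return Data frame, one row per cluster.
#' @export
reference_clusters <- function() {
  path <- system.file("extdata", "transoxiana_clusters.tsv", package = "ystr")
  read.delim(path, check.names = FALSE)
}

#' Founder haplotype of a reference cluster
#'
#' @param cluster Cluster name (e.g. `"alpha"`, `"mu"`).
#' @return A length-1 [str_haplotypes()] object.
#' @export
reference_founder <- function(cluster) {
  rc <- reference_clusters()
  row <- rc[rc$cluster == cluster, ]
  if (nrow(row) != 1) {
    ystr_abort(sprintf("unknown reference cluster '%s'", cluster),
               "ystr_validation_error")
  }
  str_haplotypes(as.integer(row[YSTR_15_LOCI]),
                 haplogroup = row$haplogroup,
                 dys19_dup = row$dys19_dup,
                 id = paste0("FOUNDER_", cluster))
}
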