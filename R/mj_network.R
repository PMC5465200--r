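#' Build a median-joining network of STR haplotypes
#'
#' Bandelt-style median joining over integer repeat profiles. Identical
#' profiles are collapsed into nodes carrying multiplicity and population
#' composition. The algorithm iterates:
#' \enumerate{
#'   \item candidate links = pairs whose step distance is within the
#'     minimum-spanning-network connection level plus `epsilon`;
#'   \item for every pair of links sharing a node, the per-locus median of
#'     the three profiles is proposed as a median (ancestral) vector;
#'   \item the proposed median that most reduces the total connection cost
#'     (minimum-spanning-tree weight of the node set) is added; repeat to
#'     fixpoint;
#'   \item median vectors with degree < 2 in the final link set are pruned.
#' }
#' All tie-breaks are lexicographic on allele vectors, so the result does not
#' depend on input order. Duplicated-DYS19 flags do not affect topology (all
#' 15 loci are compared); mixed-haplogroup input is rejected.
#'
#' @param haplotypes A [str_haplotypes()] set (single haplogroup, at least
#'   two distinct profiles).
#' @param epsilon Connection-cost slack for candidate links (default 0, the
#'   usual software default).
#' @return A `ystr_network`: node profiles, `kind` (observed/median),
#'   `multiplicity`, per-node population counts and sample ids, an edge table
#'   with per-locus changes, `epsilon`, `haplogroup`.
#' @export
build_network <- function(haplotypes, epsilon = 0) {
  hgs <- unique(haplotypes$haplogroup)
  if (length(hgs) != 1) {
    ystr_abort(sprintf("network requires a single haplogroup, got: %s",
                       paste(hgs, collapse = ", ")),
               "ystr_validation_error")
  }
  key <- profile_key(haplotypes)
  uk <- unique(key)
  if (length(uk) < 2) {
    ystr_abort("need at least two distinct profiles", "ystr_validation_error")
  }
  first <- match(uk, key)
  profiles <- haplotypes$alleles[first, , drop = FALSE]
  # lexicographic canonical node order for determinism
  ord <- do.call(order, lapply(seq_len(ncol(profiles)),
                               function(j) profiles[, j]))
  profiles <- profiles[ord, , drop = FALSE]
  uk <- uk[ord]
  grp <- match(key, uk)
  multiplicity <- tabulate(grp, length(uk))
  pop_counts <- lapply(seq_along(uk), function(i) {
    p <- haplotypes$population[grp == i]
    p <- p[!is.na(p)]
    if (!length(p)) integer(0) else {
      tt <- table(p)
      setNames(as.integer(tt), names(tt))
    }
  })
  ids <- lapply(seq_along(uk), function(i) haplotypes$id[grp == i])

  n_obs <- nrow(profiles)
  kind <- rep("observed", n_obs)

  repeat {
    D <- as.matrix(stats::dist(profiles, method = "manhattan"))
    links <- msn_links(D, epsilon)
    cost_now <- mst_cost(D)
    # propose medians for link pairs sharing a node
    cand <- collect_medians(profiles, links)
    if (!nrow(cand)) break
    red <- vapply(seq_len(nrow(cand)), function(i) {
      P2 <- rbind(profiles, cand[i, ])
      cost_now - mst_cost(as.matrix(stats::dist(P2, method = "manhattan")))
    }, numeric(1))
    best <- which(red > 1e-9)
    if (!length(best)) break
    bo <- best[do.call(order, c(list(-red[best]),
                                lapply(seq_len(ncol(cand)),
                                       function(j) cand[best, j])))][1]
    profiles <- rbind(profiles, cand[bo, , drop = FALSE])
    kind <- c(kind, "median")
    multiplicity <- c(multiplicity, 0L)
    pop_counts <- c(pop_counts, list(integer(0)))
    ids <- c(ids, list(character(0)))
  }

  # prune median vectors of degree < 2 (obsolete sequence types)
  repeat {
    D <- as.matrix(stats::dist(profiles, method = "manhattan"))
    links <- msn_links(D, epsilon)
    deg <- tabulate(c(links$from, links$to), nrow(profiles))
    drop <- which(kind == "median" & deg < 2)
    if (!length(drop)) break
    keep <- setdiff(seq_len(nrow(profiles)), drop)
    profiles <- profiles[keep, , drop = FALSE]
    kind <- kind[keep]
    multiplicity <- multiplicity[keep]
    pop_counts <- pop_counts[keep]
    ids <- ids[keep]
  }

  D <- as.matrix(stats::dist(profiles, method = "manhattan"))
  links <- msn_links(D, epsilon)
  links$weight <- D[cbind(links$from, links$to)]
  links$loci <- vapply(seq_len(nrow(links)), function(e) {
    a <- profiles[links$from[e], ]; b <- profiles[links$to[e], ]
    dd <- b - a
    ch <- which(dd != 0)
    paste(sprintf("%s:%+d", colnames(profiles)[ch], dd[ch]), collapse = ",")
  }, character(1))

  structure(list(profiles = profiles, kind = kind,
                 multiplicity = as.integer(multiplicity),
                 pop_counts = pop_counts, ids = ids,
                 edges = links, epsilon = epsilon, haplogroup = hgs),
            class = "ystr_network")
}

# epsilon-relaxed minimum-spanning-network links: pair (i,j) is a link iff
# D[i,j] <= bottleneck(i,j) + epsilon, where bottleneck is the Kruskal
# connection level (max edge on the MST path)
msn_links <- function(D, epsilon = 0) {
  n <- nrow(D)
  B <- bottleneck_matrix(D)
  sel <- which(upper.tri(D) & D <= B + epsilon + 1e-9, arr.ind = TRUE)
  data.frame(from = sel[, 1], to = sel[, 2])
}

# single-linkage merge levels via Kruskal union-find
bottleneck_matrix <- function(D) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  B <- matrix(0, n, n)
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[ut])
  comp_members <- as.list(seq_len(n))
  for (e in ord) {
    i <- ut[e, 1]; j <- ut[e, 2]
    ri <- find(i); rj <- find(j)
    if (ri != rj) {
      w <- D[i, j]
      a <- comp_members[[ri]]; b <- comp_members[[rj]]
      B[a, rep(b, each = length(a))] <- w
      B[b, rep(a, each = length(b))] <- w
      parent[rj] <- ri
      comp_members[[ri]] <- c(a, b)
      comp_members[[rj]] <- integer(0)
    }
  }
  B
}

mst_cost <- function(D) {
  n <- nrow(D)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ord <- order(D[ut])
  total <- 0
  for (e in ord) {
    ri <- find(ut[e, 1]); rj <- find(ut[e, 2])
    if (ri != rj) { total <- total + D[ut[e, 1], ut[e, 2]]; parent[rj] <- ri }
  }
  total
}

# candidate median vectors (per-locus median of linked triplets) not already
# present among the profiles
collect_medians <- function(profiles, links) {
  n <- nrow(profiles)
  adj <- lapply(seq_len(n), function(i) {
    sort(unique(c(links$to[links$from == i], links$from[links$to == i])))
  })
  have <- apply(profiles, 1, paste, collapse = "-")
  out <- list()
  for (u in seq_len(n)) {
    nb <- adj[[u]]
    if (length(nb) < 2) next
    pairs <- utils::combn(nb, 2)
    for (q in seq_len(ncol(pairs))) {
      trio <- rbind(profiles[u, ], profiles[pairs[1, q], ],
                    profiles[pairs[2, q], ])
      m <- apply(trio, 2, function(v) sort(v)[2])
      if (!(paste(m, collapse = "-") %in% have)) {
        out[[length(out) + 1L]] <- m
      }
    }
  }
  if (!length(out)) {
    return(matrix(integer(0), 0, ncol(profiles),
                  dimnames = list(NULL, colnames(profiles))))
  }
  m <- unique(do.call(rbind, out))
  colnames(m) <- colnames(profiles)
  m
}

#' Total connection cost of a network
#'
#' Minimum-spanning-tree weight over the final node set (observed plus
#' median vectors). Median joining only ever adds vectors that reduce this
#' cost, so it is bounded above by the MST cost of the observed haplotypes.
#'
#' @param net A `ystr_network`.
#' @return Numeric total cost.
#' @export
network_cost <- function(net) {
  mst_cost(as.matrix(stats::dist(net$profiles, method = "manhattan")))
}

#' Convert a median network to an igraph object
#'
#' Node attributes: `kind` (observed/median), `multiplicity`, `profile`,
#' `populations` (e.g. `"KAZ1:3;KAZ2:1"`); edge attributes: `weight` and
#' `loci` (mutated loci with signed repeat changes).
#'
#' @param net A `ystr_network`.
#' @return An igraph graph.
#' @export
as_igraph <- function(net) {
  n <- nrow(net$profiles)
  popstr <- vapply(net$pop_counts, function(pc) {
    if (!length(pc)) "" else paste(sprintf("%s:%d", names(pc), pc),
                                   collapse = ";")
  }, character(1))
  g <- igraph::graph_from_data_frame(
    net$edges[, c("from", "to")],
    directed = FALSE,
    vertices = data.frame(
      name = seq_len(n),
      kind = net$kind,
      multiplicity = net$multiplicity,
      profile = apply(net$profiles, 1, paste, collapse = "-"),
      populations = popstr))
  igraph::E(g)$weight <- net$edges$weight
  igraph::E(g)$loci <- net$edges$loci
  g
}

#' @export
print.ystr_network <- function(x, ...) {
  cat(sprintf(
    "<ystr_network: %d node(s) (%d median), %d edge(s), %d sample(s), %s>\n",
    nrow(x$profiles), sum(x$kind == "median"), nrow(x$edges),
    sum(x$multiplicity), x$haplogroup))
  invisible(x)
}

#' Delineate a population-specific descent cluster on a network
#'
#' Applies the zone -> ancestor -> clade procedure: first a connected zone of
#' the network is grown around the founder node while the cumulative fraction
#' of its samples from `seed_population` stays at or above
#' `enrichment_threshold` ("a zone carrying mostly haplotypes from a single
#' population"); the network is then rooted at the founder (modal haplotypes
#' act as founders); finally every node whose shortest path to the founder
#' stays inside the zone — and lies within `distance_cap` mutational steps —
#' contributes its samples to the cluster. Median nodes carry no samples and
#' are enrichment-neutral.
#'
#' @param net A `ystr_network`.
#' @param seed_population Population label the cluster should be enriched in.
#' @param founder A `ystr_modal` or length-1 [str_haplotypes()] whose profile
#'   must be present in the network.
#' @param enrichment_threshold Minimum zone fraction of seed-population
#'   samples (default 0.5).
#' @param distance_cap Maximum step distance from the founder (default 4,
#'   the related-search radius); more distant haplotypes are ignored.
#' @param name Optional cluster name (e.g. `"alpha"`).
#' @return A `ystr_cluster`: founder, zone and member node indices, member
#'   sample ids, `n_samples`, `enrichment`, `seed_population`.
#' @export
delineate_cluster <- function(net, seed_population, founder,
                              enrichment_threshold = 0.5,
                              distance_cap = 4, name = NA_character_) {
  hap <- if (inherits(founder, "ystr_modal")) founder$haplotype else founder
  fkey <- paste(hap$alleles[1, ], collapse = "-")
  node_keys <- apply(net$profiles, 1, paste, collapse = "-")
  f <- match(fkey, node_keys)
  if (is.na(f)) {
    ystr_abort("founder haplotype not present in the network",
               "ystr_validation_error")
  }
  n <- nrow(net$profiles)
  seed_cnt <- vapply(net$pop_counts, function(pc) {
    if (seed_population %in% names(pc)) pc[[seed_population]] else 0L
  }, integer(1))
  tot_cnt <- net$multiplicity
  adj <- lapply(seq_len(n), function(i) {
    sort(unique(c(net$edges$to[net$edges$from == i],
                  net$edges$from[net$edges$to == i])))
  })
  frac <- function(nodes) {
    tt <- sum(tot_cnt[nodes])
    if (tt == 0) 1 else sum(seed_cnt[nodes]) / tt
  }
  if (frac(f) < enrichment_threshold) {
    ystr_warn("zone empty at this enrichment threshold: empty cluster",
              "ystr_empty_zone")
    return(structure(list(name = name, founder = founder, zone = integer(0),
                          members = integer(0), member_ids = character(0),
                          n_samples = 0L, enrichment = NA_real_,
                          seed_population = seed_population,
                          distance_cap = distance_cap),
                     class = "ystr_cluster"))
  }
  # greedy zone growth: a frontier node joins only if it is itself
  # seed-population-dominated (median nodes are neutral) and the cumulative
  # zone enrichment stays above threshold; deterministic via lexicographic
  # node order on ties
  node_frac <- ifelse(tot_cnt == 0, 1, seed_cnt / pmax(tot_cnt, 1))
  zone <- f
  repeat {
    frontier <- setdiff(sort(unique(unlist(adj[zone]))), zone)
    frontier <- frontier[node_frac[frontier] >= enrichment_threshold]
    if (!length(frontier)) break
    res <- vapply(frontier, function(v) frac(c(zone, v)), numeric(1))
    ok <- res >= enrichment_threshold
    if (!any(ok)) break
    pick <- frontier[ok][order(-res[ok], frontier[ok])][1]
    zone <- c(zone, pick)
  }
  zone <- sort(zone)

  paths <- shortest_paths_det(net, f)
  in_zone_path <- vapply(seq_len(n), function(v) {
    p <- paths$path[[v]]
    length(p) > 0 && all(p %in% zone)
  }, logical(1))
  members <- which(in_zone_path & paths$dist <= distance_cap)
  structure(list(name = name, founder = founder, zone = zone,
                 members = members,
                 member_ids = unlist(net$ids[members]) %||% character(0),
                 n_samples = sum(net$multiplicity[members]),
                 enrichment = frac(zone),
                 seed_population = seed_population,
                 distance_cap = distance_cap),
            class = "ystr_cluster")
}

# Dijkstra from the founder with deterministic tie-breaks (lower cost first,
# then lexicographic node order); returns per-node distance and full path
shortest_paths_det <- function(net, from) {
  n <- nrow(net$profiles)
  w <- net$edges$weight
  adj <- vector("list", n)
  for (e in seq_len(nrow(net$edges))) {
    i <- net$edges$from[e]; j <- net$edges$to[e]
    adj[[i]] <- rbind(adj[[i]], c(j, w[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, w[e]))
  }
  dist <- rep(Inf, n); dist[from] <- 0
  parent <- rep(NA_integer_, n)
  done <- rep(FALSE, n)
  repeat {
    cand <- which(!done & is.finite(dist))
    if (!length(cand)) break
    u <- cand[order(dist[cand], cand)][1]
    done[u] <- TRUE
    if (!is.null(adj[[u]])) {
      for (r in seq_len(nrow(adj[[u]]))) {
        v <- adj[[u]][r, 1]; duv <- dist[u] + adj[[u]][r, 2]
        if (duv < dist[v] - 1e-9 ||
            (abs(duv - dist[v]) <= 1e-9 && !is.na(parent[v]) &&
             u < parent[v])) {
          dist[v] <- duv
          parent[v] <- u
        }
      }
    }
  }
  path <- lapply(seq_len(n), function(v) {
    if (!is.finite(dist[v])) return(integer(0))
    p <- v
    while (v != from) { v <- parent[v]; p <- c(v, p) }
    p
  })
  list(dist = dist, parent = parent, path = path)
}

#' @export
print.ystr_cluster <- function(x, ...) {
  cat(sprintf(
    "<ystr_cluster%s: %d node(s), %d sample(s), enrichment %.2f (%s)>\n",
    if (is.na(x$name)) "" else paste0(" ", x$name),
    length(x$members), x$n_samples,
    if (is.na(x$enrichment)) NA else x$enrichment, x$seed_population))
  invisible(x)
}
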