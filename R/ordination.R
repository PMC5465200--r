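#' Metric multidimensional scaling with stress majorization
#'
#' Embeds a distance matrix in `k` dimensions. The configuration is
#' initialised from the classical (Torgerson) solution and refined by SMACOF
#' stress majorization (Guttman transform), which makes the result
#' deterministic for a fixed input. Reported stress is Kruskal's stress-1
#' normalised by the input dissimilarities:
#' `sqrt( sum (d_ij - delta_ij)^2 / sum delta_ij^2 )`, where `delta` are the
#' input distances and `d` the configuration distances.
#'
#' @param dm A `ystr_dist` (finite entries; infinite Nei sentinels are
#'   rejected) or a plain symmetric matrix.
#' @param k Number of dimensions (default 2); must be smaller than the number
#'   of populations.
#' @param maxit,tol Majorization iteration controls.
#' @return A `ystr_ordination` with `coordinates` (centered), `stress`, `k`,
#'   and the per-iteration `stress_trace`.
#' @export
mds <- function(dm, k = 2, maxit = 500, tol = 1e-12) {
  delta <- if (inherits(dm, "ystr_dist")) dm$d else as.matrix(dm)
  n <- nrow(delta)
  if (any(!is.finite(delta))) {
    ystr_abort(
      "distance matrix contains non-finite entries (infinite Nei sentinel?)",
      "ystr_validation_error")
  }
  if (k >= n) {
    ystr_abort("k must be smaller than the number of populations",
               "ystr_validation_error")
  }
  X <- classical_init(delta, k)
  denom <- sum(delta^2)
  if (denom == 0) {
    ystr_abort("all distances are zero", "ystr_validation_error")
  }
  raw_stress <- function(X) {
    d <- as.matrix(stats::dist(X))
    sum((delta - d)[upper.tri(delta)]^2)
  }
  s_prev <- raw_stress(X)
  trace <- numeric(0)
  for (it in seq_len(maxit)) {
    d <- as.matrix(stats::dist(X))
    B <- ifelse(d > 0, -delta / ifelse(d > 0, d, 1), 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
    s <- raw_stress(X)
    trace <- c(trace, s)
    if (s_prev - s < tol * max(1, s_prev)) break
    s_prev <- s
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  rownames(X) <- rownames(delta)
  colnames(X) <- paste0("Dim", seq_len(k))
  d <- as.matrix(stats::dist(X))
  stress1 <- sqrt(sum((d - delta)[upper.tri(delta)]^2) /
                    sum(delta[upper.tri(delta)]^2))
  structure(list(coordinates = X, stress = stress1, k = k,
                 method = "mds_majorization", stress_trace = trace),
            class = "ystr_ordination")
}

# Torgerson double-centering; pads with zero axes when the matrix supports
# fewer than k positive eigenvalues
classical_init <- function(delta, k) {
  n <- nrow(delta)
  fit <- suppressWarnings(cmdscale(delta, k = min(k, n - 1), eig = TRUE))
  X <- fit$points
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  if (ncol(X) < k) {
    X <- cbind(X, matrix(0, n, k - ncol(X)))
  }
  X
}

#' Principal component analysis of haplogroup frequencies
#'
#' Eigen-decomposition of the covariance matrix of centered frequency rows.
#' Components are ordered by decreasing variance; each component's sign is
#' fixed so that its largest-magnitude loading is positive.
#'
#' @param ft A [frequency_table()] (or plain numeric matrix, rows =
#'   populations).
#' @param k Number of components to return.
#' @return A `ystr_ordination` with `coordinates` (scores), `explained`
#'   (variance fractions over all components), `loadings`, `k`.
#' @export
pca <- function(ft, k = 2) {
  P <- if (inherits(ft, "ystr_freq")) ft$p else as.matrix(ft)
  n <- nrow(P)
  if (n < 2) ystr_abort("PCA needs at least 2 populations",
                        "ystr_validation_error")
  k <- min(k, ncol(P), n - 1)
  Pc <- scale(P, center = TRUE, scale = FALSE)
  C <- crossprod(Pc) / (n - 1)
  eig <- eigen(C, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  tot <- sum(vals)
  load <- eig$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (load[which.max(abs(load[, j])), j] < 0) load[, j] <- -load[, j]
  }
  scores <- Pc %*% load
  rownames(scores) <- rownames(P)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(load) <- colnames(P)
  colnames(load) <- colnames(scores)
  structure(list(coordinates = scores,
                 explained = if (tot > 0) vals / tot else rep(0, length(vals)),
                 loadings = load, k = k, method = "pca"),
            class = "ystr_ordination")
}

#' @export
print.ystr_ordination <- function(x, ...) {
  cat(sprintf("<ystr_ordination (%s), k = %d>\n", x$method, x$k))
  if (!is.null(x$stress)) cat(sprintf("stress-1 = %.4f\n", x$stress))
  if (!is.null(x$explained)) {
    cat("explained variance:",
        paste(sprintf("%.1f%%", 100 * head(x$explained, x$k)),
              collapse = " "), "\n")
  }
  print(round(x$coordinates, 4))
  invisible(x)
}
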