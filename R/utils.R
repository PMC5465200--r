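# internal helpers: classed errors, deterministic formatting, Dirichlet draws

ystr_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "ystr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ystr_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "ystr_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# fixed-format numbers for deterministic text output: 6 significant digits,
# no scientific notation drift across platforms
fmt_num <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), ifelse(x > 0, "Inf", "-Inf"),
                formatC(signif(x, 6), format = "g", digits = 6)))
}

# Dirichlet sampler via normalised gammas; alpha may contain zeros (mass 0)
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[which.max(alpha)] <- 1 # degenerate tiny-alpha guard
  x / sum(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
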