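# Internal helpers: seeded evaluation, per-row seed derivation, weighted
# quantiles, and a small config hash.

# Evaluate expr under a temporary RNG state; restores .Random.seed on exit.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic per-row seed: a splitmix-style integer mix of (master, index),
# independent of chunking so chunked and monolithic generation agree.
# Returns values in [1, 2^31 - 2].
deriveSeed <- function(master, index) {
  m <- 2147483647  # 2^31 - 1, prime
  x <- (as.numeric(master) %% m)
  out <- numeric(length(index))
  for (k in seq_along(index)) {
    z <- (x * 48271 + as.numeric(index[k]) * 69621 + 1) %% m
    z <- (z * 16807) %% m
    z <- (z * 48271 + 12345) %% m
    out[k] <- z
  }
  as.integer(out %% (m - 2) + 1)
}

# Weighted quantile with linear interpolation at plotting positions
# (cumw - w/2)/sum(w); reduces to stats::median for uniform weights.
weightedQuantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L) return(rep(NA_real_, length(probs)))
  o <- order(x)
  x <- x[o]; w <- w[o]
  if (sum(w) <= 0) w <- rep(1, length(x))
  cw <- cumsum(w)
  p <- (cw - w / 2) / sum(w)
  vapply(probs, function(q) {
    if (q <= p[1]) return(x[1])
    if (q >= p[length(p)]) return(x[length(x)])
    stats::approx(p, x, xout = q, ties = "ordered")$y
  }, numeric(1))
}

# FNV-1a hash over a canonical character rendering; returns 8 hex chars.
configHash <- function(x) {
  s <- paste(deparse(x, control = "exact"), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Genotype matrix sanity: values in {0,1,2,NA}.
checkGenotypeMatrix <- function(g) {
  if (!is.matrix(g)) stop("genotypes must be a matrix (sites x individuals)")
  v <- g[!is.na(g)]
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    stop("genotype values must be in {0, 1, 2, NA}")
  invisible(TRUE)
}
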