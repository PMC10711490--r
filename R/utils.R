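# Internal numeric helpers. RNG discipline: every stochastic routine takes a
# seed and runs under withSeed(), so library calls never disturb the caller's
# RNG state and identical (params, seed) pairs give identical output.

withSeed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Counter-based substream: per-image / per-tile seeds derived from one global
# seed so outputs are independent of generation order. Kept within exact
# double-integer range and below 2^31 for set.seed().
substreamSeed <- function(seed, index) {
  s <- as.double(seed %% 2147483629)
  as.integer((s * 69069 + as.double(index) * 10007) %% 2147483629)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

asPixels <- function(x) {
  # numeric [0,1] array -> 8-bit integer array
  storage.mode(x) <- "integer"
  x
}

quantize255 <- function(x) {
  y <- as.integer(round(clamp(x, 0, 1) * 255))
  dim(y) <- dim(x)
  y
}

# Mean-pool a matrix by integer factor f along both axes (dims divisible by f).
poolMat <- function(m, f) {
  if (f == 1L) return(m)
  H <- nrow(m); W <- ncol(m)
  dim(m) <- c(f, H %/% f, W)
  m2 <- t(colMeans(m))            # W x H/f
  dim(m2) <- c(f, W %/% f, H %/% f)
  t(colMeans(m2))                 # H/f x W/f
}

# Simple separable box blur (repeated = approximately Gaussian), used by the
# texture generator. Edges use shrinking windows via cumulative sums.
boxBlur <- function(m, radius, passes = 2L) {
  for (p in seq_len(passes)) {
    m <- blurAxis(m, radius)
    m <- t(blurAxis(t(m), radius))
  }
  m
}

blurAxis <- function(m, r) {
  n <- nrow(m)
  cs <- rbind(0, apply(m, 2, cumsum))
  i <- seq_len(n)
  lo <- pmax(i - r, 1L); hi <- pmin(i + r, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

stopIfNot01 <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]", call. = FALSE)
}
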