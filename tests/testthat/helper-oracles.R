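# Independent brute-force oracles. These deliberately re-derive each
# quantity from its definition with plain loops, sharing no code with the
# package implementations they check.

bruteAveragePrecision <- function(scores, labels) {
  P <- sum(labels == 1)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  ap <- 0
  prevRecall <- 0
  for (t in thresholds) {
    pred <- scores >= t
    precision <- sum(labels[pred] == 1) / sum(pred)
    recall <- sum(labels[pred] == 1) / P
    ap <- ap + (recall - prevRecall) * precision
    prevRecall <- recall
  }
  ap
}

bruteAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

bruteBestDice <- function(scores, labels) {
  best <- -1
  for (t in sort(unique(c(0, 1, scores)))) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(scores)) {
      pred <- scores[i] >= t
      if (pred && labels[i] == 1) tp <- tp + 1
      if (pred && labels[i] == 0) fp <- fp + 1
      if (!pred && labels[i] == 1) fn <- fn + 1
    }
    d <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    if (d > best) best <- d
  }
  best
}

# Exact two-sided signed-rank p-value by dynamic programming over the null
# distribution of W+ (all 2^n sign assignments); requires no zero
# differences and no tied |differences|.
wilcoxExactP <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  # counts[k+1] = number of sign assignments with W+ == k
  counts <- c(1, rep(0, n * (n + 1) / 2))
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), counts)[seq_along(counts)]
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  lo <- sum(probs[seq_len(floor(w) + 1)])          # P(W <= w)
  hi <- sum(probs[(floor(w) + 1):length(probs)])   # P(W >= w)
  min(1, 2 * min(lo, hi))
}

# Fleiss' kappa from an items x categories count table, written directly
# from the definition.
fleissOracle <- function(N) {
  n <- sum(N[1, ])
  Pi <- apply(N, 1, function(row) (sum(row^2) - n) / (n * (n - 1)))
  Pbar <- mean(Pi)
  pj <- apply(N, 2, sum) / sum(N)
  (Pbar - sum(pj^2)) / (1 - sum(pj^2))
}

# Brute-force sliding-window map: enumerates every window by a while-loop,
# scores it with `probFun(crop)`, and assigns it to each cell by explicit
# containment inequalities.
oracleProbabilityMap <- function(pixels, tileSize, stride, probFun) {
  H <- dim(pixels)[1]; W <- dim(pixels)[2]
  origins <- function(dim) {
    o <- c(); r <- 0
    while (r + tileSize <= dim) { o <- c(o, r); r <- r + stride }
    if (o[length(o)] != dim - tileSize) o <- c(o, dim - tileSize)
    o
  }
  nR <- ceiling(H / stride); nC <- ceiling(W / stride)
  tot <- matrix(0, nR, nC); cnt <- matrix(0L, nR, nC)
  for (r in origins(H)) for (cc in origins(W)) {
    crop <- pixels[(r + 1):(r + tileSize), (cc + 1):(cc + tileSize), ,
                   drop = FALSE]
    p <- probFun(crop)
    for (a in seq_len(nR)) for (b in seq_len(nC)) {
      rs <- (a - 1) * stride; re <- min(a * stride, H)
      cs <- (b - 1) * stride; ce <- min(b * stride, W)
      if (rs >= r && re <= r + tileSize && cs >= cc && ce <= cc + tileSize) {
        tot[a, b] <- tot[a, b] + p
        cnt[a, b] <- cnt[a, b] + 1L
      }
    }
  }
  list(values = tot / cnt, counts = cnt)
}

# random score/label instance with both classes present; optionally ties
randomScoredInstance <- function(n, tie = FALSE) {
  repeat {
    scores <- if (tie) round(runif(n), 1) else runif(n)
    labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(labels) > 0 && sum(labels) < n) return(list(s = scores, y = labels))
  }
}
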