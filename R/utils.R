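## Internal helpers shared across modules.

## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream.
withSeed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

## Derive a reproducible per-stage seed from a root seed and a stage name.
## Polynomial string hash combined with the root via a multiplicative LCG
## step, all mod 2^31 - 1 so the result is a valid 32-bit R integer.
stageSeed <- function(rootSeed, stage) {
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(((as.numeric(rootSeed) %% m) * 48271 + h) %% m)
}

## All permutations of 1..n as an n! x n matrix (n <= 8 guarded by callers).
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      perm <- integer(n)
      perm[k] <- n
      perm[-k] <- sub[i, ]
      out[row, ] <- perm
      row <- row + 1L
    }
  }
  out
}

## Euclidean distance matrix between two sets of (x, y) points.
crossDist <- function(a, b) {
  dx <- outer(a[, 1L], b[, 1L], "-")
  dy <- outer(a[, 2L], b[, 2L], "-")
  sqrt(dx * dx + dy * dy)
}

## Logical disk mask helpers -------------------------------------------------

## Squared distance (in pixels) of every pixel center from (cx, cy), given in
## pixel units; returns a matrix matching nrow x ncol.
pixelDist2 <- function(nrow, ncol, cx, cy) {
  xs <- (seq_len(ncol) - 1) - cx
  ys <- (seq_len(nrow) - 1) - cy
  outer(ys * ys, xs * xs, "+")
}

## Write a data.frame as CSV with stable formatting.
writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
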