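# Independent brute-force oracles used by several test files.

# O(n^2) brute-force oracle: enumerate every pair, keep all maximizers,
# return the lexicographically smallest canonical quadruple
bruteFarthest <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
  n <- length(x)
  qs <- list(); bd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d2 <- (x[i] - x[j])^2 + (y[i] - y[j])^2
    if (d2 < bd) next
    a <- c(x[i], y[i]); b <- c(x[j], y[j])
    q <- if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) c(b, a) else
      c(a, b)
    if (d2 > bd) { bd <- d2; qs <- list(q) } else qs[[length(qs) + 1]] <- q
  }
  qm <- do.call(rbind, qs)
  list(q = unname(qm[order(qm[, 1], qm[, 2], qm[, 3], qm[, 4])[1], ]),
       d = sqrt(bd))
}

# all-pairs quantile oracle on surface voxels
bruteHd95 <- function(a, b, spacing = c(1, 1, 1)) {
  pa <- cunet:::.surfaceCoords(a, spacing)
  pb <- cunet:::.surfaceCoords(b, spacing)
  dmat <- sqrt(pmax(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                      2 * pa %*% t(pb), 0))
  unname(quantile(c(apply(dmat, 1, min), apply(dmat, 2, min)), 0.95,
                  type = 7))
}

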