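# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: dense normal-equations solves, elementwise loops,
# and brute-force overlap integration.

# ridge solution via an explicit dense normal-equations solve
oracle_ridge <- function(H, Y, lambda) {
  solve(t(H) %*% H + lambda * diag(ncol(H)), t(H) %*% Y)
}

# minimum-norm least squares via MASS's pseudo-inverse
oracle_pinv <- function(H, Y) MASS::ginv(H) %*% Y

# block downsampling by explicit per-pixel overlap integration in 2-D
oracle_downsample <- function(x, target) {
  side <- nrow(x)
  s <- side / target
  out <- matrix(0L, target, target)
  for (i in seq_len(target)) for (j in seq_len(target)) {
    rlo <- (i - 1) * s; rhi <- i * s
    clo <- (j - 1) * s; chi <- j * s
    tot <- 0; wsum <- 0
    for (r in floor(rlo):(ceiling(rhi) - 1)) for (cc in floor(clo):(ceiling(chi) - 1)) {
      w <- max(0, min(rhi, r + 1) - max(rlo, r)) *
           max(0, min(chi, cc + 1) - max(clo, cc))
      if (w > 0) {
        tot <- tot + w * x[r + 1, cc + 1]
        wsum <- wsum + w
      }
    }
    if (tot / wsum >= 0.5) out[i, j] <- 1L
  }
  out
}

# count pixels whose center falls inside a circle, by direct scan
oracle_circle_count <- function(side, cx, cy, radius) {
  n <- 0L
  for (r in seq_len(side)) for (cc in seq_len(side)) {
    if ((cc - 0.5 - cx)^2 + (r - 0.5 - cy)^2 <= radius^2) n <- n + 1L
  }
  n
}

# l1-regularized objective, written out directly
oracle_l1_objective <- function(A, X, B, lambda) {
  0.5 * sum((A %*% B - X)^2) + lambda * sum(abs(B))
}

# build a tiny BUSI-style directory tree of PNGs; returns its root
make_tiny_busi <- function(n_per_class = 2L, side = 64L, seed = 42L) {
  root <- withr::local_tempdir(.local_envir = parent.frame())
  spec <- helmus::synth_spec(n_per_class = n_per_class, image_side = side,
                             seed = seed)
  helmus::write_synth_busi(spec, root)
  root
}
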