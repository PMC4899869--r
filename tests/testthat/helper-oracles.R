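# Pure-R brute-force oracles, deliberately independent of the package's
# compiled distance kernels.

bf_nn <- function(sx, sy, tx, ty) {
  vapply(seq_along(sx), function(i)
    min(sqrt((sx[i] - tx)^2 + (sy[i] - ty)^2)), numeric(1))
}

bf_nn_self <- function(x, y) {
  vapply(seq_along(x), function(i)
    min(sqrt((x[i] - x[-i])^2 + (y[i] - y[-i])^2)), numeric(1))
}

bf_region <- function(sx, sy, region) {
  idx <- which(region != 0, arr.ind = TRUE)
  bf_nn(sx, sy, idx[, 2] - 1, idx[, 1] - 1)
}

rand_points <- function(n, shape, class = "test") {
  point_set(runif(n, 0, shape[2] - 1), runif(n, 0, shape[1] - 1),
            cell_class = class, provenance = "simulated")
}

full_mask <- function(nr, nc = nr) region_mask(matrix(TRUE, nr, nc))

# Greedy nearest-first matching of detections to ground truth within a
# pixel tolerance; returns the F1 score.
match_f1 <- function(det, truth, tol = 3) {
  nd <- nrow(det); nt <- nrow(truth)
  if (nd == 0 || nt == 0) return(0)
  used <- rep(FALSE, nt); tp <- 0
  for (i in seq_len(nd)) {
    d2 <- (det$x[i] - truth$x)^2 + (det$y[i] - truth$y)^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (d2[j] <= tol^2) { used[j] <- TRUE; tp <- tp + 1 }
  }
  2 * tp / (nd + nt)
}
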