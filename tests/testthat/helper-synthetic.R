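# Shared fixtures and independent oracles, all built in code.

# Rasterized shapes on pixel grids (row = y, col = x).
raster_disk <- function(n, radius, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  xs <- matrix(rep(seq_len(n), each = n), n, n)
  ys <- matrix(rep(seq_len(n), n), n, n)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

raster_ellipse <- function(n, a, b, angle_deg = 0) {
  c0 <- (n + 1) / 2
  xs <- matrix(rep(seq_len(n), each = n), n, n) - c0
  ys <- matrix(rep(seq_len(n), n), n, n) - c0
  th <- angle_deg * pi / 180
  u <- xs * cos(th) + ys * sin(th)
  v <- -xs * sin(th) + ys * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

as_labels <- function(mask, kind = "nuclei") {
  label_map(matrix(as.integer(mask), nrow(mask)), kind)
}

# Ramanujan perimeter approximation for an ellipse (oracle for circularity).
ramanujan_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

# Continuous closed-form phasor of a mono-exponential decay; verified
# against brute-force numerical integration in the phasor tests.
phasor_closed_form <- function(tau, k, period = 50) {
  w <- 2 * pi * k / period
  c(g = 1 / (1 + (w * tau)^2), s = w * tau / (1 + (w * tau)^2))
}

# Brute-force phasor by fine numerical integration of the continuous decay
# (independent of the package's binned transform).
phasor_numeric <- function(tau, k, period = 50, n = 2e5) {
  t <- (seq_len(n) - 0.5) * period / n
  f <- exp(-t / tau)
  w <- 2 * pi * k / period
  c(g = sum(f * cos(w * t)) / sum(f), s = sum(f * sin(w * t)) / sum(f))
}

# Brute-force multi-source geodesic distance by breadth-first relaxation
# (8-connected, exact Dijkstra on the pixel graph); oracle for
# propagate_cells in the uniform-intensity limit.
bfs_geodesic_labels <- function(fg, seeds) {
  nr <- nrow(fg); nc <- ncol(fg)
  dist <- matrix(Inf, nr, nc)
  lab <- matrix(0L, nr, nc)
  active <- which(seeds > 0)
  dist[active] <- 0
  lab[active] <- seeds[active]
  offs <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  steps <- sqrt(offs[, 1]^2 + offs[, 2]^2)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(offs))) {
      for (idx in which(fg)) {
        i <- ((idx - 1) %% nr) + 1; j <- ((idx - 1) %/% nr) + 1
        ni <- i + offs[k, 1]; nj <- j + offs[k, 2]
        if (ni < 1 || ni > nr || nj < 1 || nj > nc) next
        if (!fg[ni, nj] && seeds[ni, nj] == 0) next
        cand <- dist[ni, nj] + steps[k]
        if (cand < dist[i, j] - 1e-12) {
          dist[i, j] <- cand
          lab[i, j] <- lab[ni, nj]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  list(dist = dist, labels = lab)
}

# Jaccard overlap between a predicted label and the best-matching truth label.
jaccard_best <- function(pred_mask, truth_labels) {
  ids <- setdiff(unique(as.vector(truth_labels)), 0L)
  best <- 0
  for (id in ids) {
    t <- truth_labels == id
    j <- sum(pred_mask & t) / sum(pred_mask | t)
    best <- max(best, j)
  }
  best
}
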