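# Independent brute-force oracle for the surface Dice: border detection via
# array shifts in plain R, distances by exhaustive all-pairs comparison of
# squared physical distances. Shares no code with the package's C++ path.

oracle_border <- function(g) {
  d <- dim(g)
  p <- array(FALSE, d + 2)
  p[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- g
  interior <-
    p[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] & p[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] & p[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    p[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] & p[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  g & !interior
}

oracle_surface_points <- function(vol) {
  idx <- which(oracle_border(vol$grid))
  sweep(arrayInd(idx, dim(vol$grid)) - 1, 2, vol$spacing_mm, "*")
}

oracle_surface_dice <- function(a, b, tol_mm) {
  pa <- oracle_surface_points(a)
  pb <- oracle_surface_points(b)
  na <- nrow(pa)
  nb <- nrow(pb)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  d2 <- matrix(0, na, nb)
  for (k in 1:3) d2 <- d2 + outer(pa[, k], pb[, k], function(x, y) (x - y)^2)
  t2 <- tol_mm^2
  (sum(apply(d2, 1, min) <= t2) + sum(apply(d2, 2, min) <= t2)) / (na + nb)
}

# random test masks: a blend of random solid blocks/balls and salt noise, so
# surfaces range from compact to fragmented and may touch the grid edge
random_mask <- function(dims, spacing, p_noise = 0.1, n_blobs = 2) {
  g <- array(stats::runif(prod(dims)) < p_noise, dims)
  for (b in seq_len(n_blobs)) {
    if (stats::runif(1) < 0.5) { # block
      lo <- pmax(1, floor(stats::runif(3) * dims))
      hi <- pmin(dims, lo + floor(stats::runif(3) * dims / 2))
      g[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    } else { # ball in physical mm
      ctr <- stats::runif(3) * (dims - 1) * spacing
      r <- stats::runif(1, 0.5, max(1, min((dims - 1) * spacing) / 2))
      ax <- lapply(1:3, function(k) ((seq_len(dims[k]) - 1) * spacing[k] - ctr[k])^2)
      g <- g | (outer(outer(ax[[1]], ax[[2]], "+"), ax[[3]], "+") <= r^2)
    }
  }
  binary_volume(g, spacing_mm = spacing)
}
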