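# Independent oracle implementations used to check the package's fast paths.
# These are deliberately naive (double loops, brute force) and share no code
# with the implementation under test.

# Moran's I with rook (4-neighbour) weights by direct double sum
morans_i_oracle <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  mu <- mean(m)
  dev <- m - mu
  num <- 0; w_sum <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      ii <- i + d[1]; jj <- j + d[2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc) {
        num <- num + dev[i, j] * dev[ii, jj]
        w_sum <- w_sum + 1
      }
    }
  }
  (nr * nc / w_sum) * num / sum(dev^2)
}

# brute-force nearest-source Euclidean distance in metres
distance_oracle <- function(mask) {
  m <- mask$values
  src <- which(m == 1, arr.ind = TRUE)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    out[i, j] <- sqrt(min((src[, 1] - i)^2 + (src[, 2] - j)^2))
  }
  out * mask$cellsize
}

# trapezoid partial-AUC ratio from an explicit (area fraction, sensitivity)
# curve restricted to sensitivity >= 1 - E
proc_oracle <- function(area_frac, sens, E) {
  keep <- which(sens >= 1 - E)
  x <- area_frac[keep]; y <- sens[keep]
  o <- order(x); x <- x[o]; y <- y[o]
  pauc <- 0
  for (i in seq_len(length(x) - 1))
    pauc <- pauc + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  pauc / ((max(x)^2 - min(x)^2) / 2)
}

# AICc by the direct formula, with the log-likelihood accumulated through
# a product (valid for the small n used in oracle cases)
aicc_oracle <- function(raw_at_occ, k) {
  n <- length(raw_at_occ)
  if (n <= k + 1) return(Inf)
  lnL <- log(prod(raw_at_occ))
  2 * k - 2 * lnL + 2 * k * (k + 1) / (n - k - 1)
}

# small all-ones region mask matching a template grid
full_mask <- function(template) {
  rg_like(template, matrix(1, nrow(template$values), ncol(template$values)))
}

# quick landscape config for tests
quick_config <- function(seed = 1, w = 64, h = 64, ...) {
  landscape_config(grid_width = w, grid_height = h, seed = seed, ...)
}
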