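# Brute-force reference implementation of the bridge-kernel UD, written
# independently of the package internals: plain loops, every kernel summed
# over every cell with no truncation. Used to pin down the optimized grid
# builder on tiny tracks.
oracle_brb_ud <- function(track, params) {
  f <- track$fixes
  hmin2 <- params$hmin^2
  D <- params$diffusion_D
  stopifnot(!is.null(D), !is.null(params$Tmax))  # oracle wants them fixed

  # enumerate kernels: (x, y, sigma2, weight)
  ker <- list()
  if (nrow(f) == 1) {
    ker[[1]] <- c(f$x, f$y, hmin2, 1)
  } else {
    for (i in seq_len(nrow(f) - 1)) {
      Tt <- as.numeric(difftime(f$timestamp[i + 1], f$timestamp[i],
                                units = "secs"))
      L <- sqrt((f$x[i + 1] - f$x[i])^2 + (f$y[i + 1] - f$y[i])^2)
      if (Tt <= params$Tmax && L >= params$Lmin) {
        for (s in seq_len(params$n_substeps)) {
          p <- (s - 0.5) / params$n_substeps
          ker[[length(ker) + 1]] <- c(
            f$x[i] + p * (f$x[i + 1] - f$x[i]),
            f$y[i] + p * (f$y[i + 1] - f$y[i]),
            hmin2 + 4 * D * Tt * p * (1 - p),
            Tt / params$n_substeps)
        }
      } else {
        ker[[length(ker) + 1]] <- c(f$x[i], f$y[i], hmin2, Tt / 2)
        ker[[length(ker) + 1]] <- c(f$x[i + 1], f$y[i + 1], hmin2, Tt / 2)
      }
    }
  }

  # same grid geometry as the package builder
  cs <- params$cell_size
  xmin <- floor((min(f$x) - params$extent_pad) / cs) * cs
  ymin <- floor((min(f$y) - params$extent_pad) / cs) * cs
  xmax <- ceiling((max(f$x) + params$extent_pad) / cs) * cs
  ymax <- ceiling((max(f$y) + params$extent_pad) / cs) * cs
  n_cols <- round((xmax - xmin) / cs)
  n_rows <- round((ymax - ymin) / cs)

  mass <- matrix(0, n_rows, n_cols)
  for (i in seq_len(n_rows)) {
    yc <- ymin + (i - 0.5) * cs
    for (j in seq_len(n_cols)) {
      xc <- xmin + (j - 0.5) * cs
      tot <- 0
      for (k in ker) {
        s2 <- k[3]
        tot <- tot + k[4] / (2 * pi * s2) *
          exp(-((xc - k[1])^2 + (yc - k[2])^2) / (2 * s2))
      }
      mass[i, j] <- tot
    }
  }
  mass / sum(mass)
}
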