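#' Dominant wavelength of a periodic concentration series
#'
#' Discrete Fourier transform index of spatial scale: with
#' `F(k) = (1/N) sum_n c_n exp(-2*pi*i*k*n/N)`, the dominant wavenumber
#' `k1` maximizes the spectral intensity `|F(k)|^2` over `k` in
#' `[1, N/2]`, and the wavelength is `L1 = N / k1`, which always lies in
#' `[2, N]`. Ties are broken toward the smallest `k` (longest wavelength)
#' and flagged.
#'
#' @param series numeric vector of concentrations on a periodic 1D array
#'   (length at least 4).
#' @return A list with `k1`, `L1`, `defined` (FALSE for a constant series,
#'   where every non-zero mode vanishes), and `tie` (TRUE when several
#'   wavenumbers share the maximal intensity).
#' @examples
#' n <- 0:199
#' wavelength_L1(cos(2 * pi * 10 * n / 200))  # k1 = 10, L1 = 20
#' @export
wavelength_L1 <- function(series) {
  N <- length(series)
  if (N < 4) stop("series too short for a spectral wavelength (N < 4)")
  intensity <- Mod(stats::fft(series) / N)^2
  ks <- seq_len(floor(N / 2))           # k = 1 .. N/2
  I <- intensity[ks + 1L]
  scale <- max(I)
  if (scale <= max(1e-28, 1e-24 * mean(series)^2))
    return(list(k1 = NA_integer_, L1 = NA_real_, defined = FALSE,
                tie = FALSE))
  top <- which(I >= scale * (1 - 1e-12))
  k1 <- ks[top[1L]]
  list(k1 = k1, L1 = N / k1, defined = TRUE, tie = length(top) > 1L)
}

#' Mean auxin-cluster size of a periodic series
#'
#' Positions with concentration strictly above the series mean are "auxin
#' spots"; maximal runs of consecutive spots (with wrap-around, so a run
#' crossing the end of the array counts once) are "auxin clusters". The
#' index `L2` is the number of spots divided by the number of clusters.
#'
#' @param series numeric vector (length at least 2).
#' @return A list with `n_spots`, `n_clusters`, `L2`, `spot_mask`, and
#'   `defined` (FALSE when no position exceeds the mean).
#' @examples
#' cluster_size_L2(rep(c(1, 1, 0, 0), 10))  # blocks of 2: L2 = 2
#' @export
cluster_size_L2 <- function(series) {
  N <- length(series)
  if (N < 2) stop("series too short (N < 2)")
  spots <- series > mean(series)
  n_spots <- sum(spots)
  if (n_spots == 0L)
    return(list(n_spots = 0L, n_clusters = 0L, L2 = NA_real_,
                spot_mask = spots, defined = FALSE))
  if (n_spots == N) {
    n_clusters <- 1L
  } else {
    # clusters = number of rising edges on the periodic mask
    prev <- spots[c(N, seq_len(N - 1L))]
    n_clusters <- sum(spots & !prev)
  }
  list(n_spots = n_spots, n_clusters = n_clusters,
       L2 = n_spots / n_clusters, spot_mask = spots, defined = TRUE)
}

#' Pattern metrics of a 1D series
#'
#' Combines [wavelength_L1()] and [cluster_size_L2()]; `patterned` is TRUE
#' when the spectral wavelength is defined and the relative spatial
#' variation exceeds `flat_tol` (a uniform final state has no pattern even
#' though floating-point residue gives a formal spectrum).
#'
#' @param series numeric vector.
#' @param flat_tol relative standard deviation below which the series is
#'   treated as uniform.
#' @return A list of class `"pattern_metrics"` with `k1`, `L1`, `L2`,
#'   `n_spots`, `n_clusters`, `patterned`, `tie`.
#' @export
pattern_metrics <- function(series, flat_tol = 1e-4) {
  l1 <- wavelength_L1(series)
  l2 <- cluster_size_L2(series)
  rel_sd <- stats::sd(series) / max(abs(mean(series)), 1e-300)
  structure(list(k1 = l1$k1, L1 = l1$L1, L2 = l2$L2,
                 n_spots = l2$n_spots, n_clusters = l2$n_clusters,
                 patterned = isTRUE(l1$defined) && rel_sd > flat_tol,
                 tie = l1$tie, rel_sd = rel_sd),
            class = "pattern_metrics")
}

#' @export
print.pattern_metrics <- function(x, ...) {
  if (!x$patterned) cat("pattern metrics: uniform (no pattern)\n")
  else cat(sprintf(
    "pattern metrics: k1 = %d, L1 = %.3g, L2 = %.3g (%d spots / %d clusters)\n",
    x$k1, x$L1, x$L2, x$n_spots, x$n_clusters))
  invisible(x)
}

#' Adjacent-cell concentration correlation
#'
#' Pearson correlation of the concentrations of the two cells flanking
#' each interface. Patterns whose features span several cells give a
#' strongly positive value; interface-scale speckle (neighboring cells
#' effectively independent or anti-correlated) gives a value near or
#' below zero. This is the scale diagnostic used for 2D sheets, where an
#' above-mean spot mask percolates at ~50% occupancy regardless of
#' spatial scale and cluster sizes alone cannot distinguish speckle from
#' structure.
#'
#' @param lattice an `auxin_lattice`.
#' @param values per-cell concentrations.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
neighbor_correlation <- function(lattice, values) {
  stopifnot(length(values) == lattice$n_cells)
  e <- lattice$edge_cells
  stats::cor(values[e[, 1L]], values[e[, 2L]])
}

#' Above-mean cluster statistics on a 2D lattice
#'
#' The 2D analogue of the cluster index: cells strictly above the mean
#' concentration are spots, and clusters are connected components of the
#' spot set under the lattice adjacency. Used to judge whether a hexagonal
#' sheet shows isolated auxin maxima (several clusters, each a small
#' fraction of the sheet) or only interface-scale speckle.
#'
#' @param lattice an `auxin_lattice` (typically a hex torus).
#' @param values per-cell concentrations.
#' @return A list with `n_spots`, `n_clusters`, `mean_size`, `max_size`,
#'   and `spot_mask`.
#' @export
cluster_stats_2d <- function(lattice, values) {
  stopifnot(length(values) == lattice$n_cells)
  spots <- which(values > mean(values))
  if (length(spots) == 0L)
    return(list(n_spots = 0L, n_clusters = 0L, mean_size = NA_real_,
                max_size = 0L, spot_mask = logical(lattice$n_cells)))
  edges <- lattice$edge_cells
  keep <- edges[, 1L] %in% spots & edges[, 2L] %in% spots
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = match(edges[keep, 1L], spots),
                   to = match(edges[keep, 2L], spots)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(spots)))
  comp <- igraph::components(g)
  sizes <- as.integer(comp$csize)
  mask <- logical(lattice$n_cells); mask[spots] <- TRUE
  list(n_spots = length(spots), n_clusters = comp$no,
       mean_size = mean(sizes), max_size = max(sizes), spot_mask = mask)
}
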