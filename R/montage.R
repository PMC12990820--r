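# 128-channel geodesic sensor net: positions, neighbour graph, named subsets.

#' Load the 128-channel geodesic sensor montage
#'
#' Reads the published sensor coordinates of the 128-channel HydroCel
#' geodesic net shipped with the package and derives a symmetric k-nearest
#' neighbour adjacency used for channel interpolation. Two occipital subsets
#' are attached: the 10-channel medial occipital set used for valid-trial
#' selection (channels 69, 70, 73, 74, 75, 81, 82, 83, 88, 89) and the
#' 3-channel region of interest (74, 75, 82) used for trial-level SNR
#' summaries.
#'
#' @param k Number of nearest neighbours per channel (default 6).
#' @return Object of class `montage`: list with `positions` (tibble:
#'   `channel`, `x`, `y`, `z`), `adjacency` (symmetric logical matrix),
#'   `occ10`, `occ3`, and `n_channels`.
#' @export
load_montage <- function(k = 6L) {
  path <- system.file("extdata", "gsn_hydrocel_128.csv", package = "freqtagsl")
  pos <- readr::read_csv(path, show_col_types = FALSE)
  xyz <- as.matrix(pos[, c("x", "y", "z")])
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    nb <- order(d[i, ])[2:(k + 1L)]
    adj[i, nb] <- TRUE
  }
  adj <- adj | t(adj) # symmetrize: neighbourhood is mutual
  dimnames(adj) <- list(pos$channel, pos$channel)
  structure(
    list(
      positions = pos,
      adjacency = adj,
      occ10 = c(69L, 70L, 73L, 74L, 75L, 81L, 82L, 83L, 88L, 89L),
      occ3 = c(74L, 75L, 82L),
      n_channels = n
    ),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage>", x$n_channels, "channels;",
      sum(x$adjacency) / 2, "neighbour edges\n")
  invisible(x)
}

# Spatial gain profile peaked on the medial occipital cluster: Gaussian in
# sensor space around the centroid of the 3-channel ROI.
occipital_gain <- function(montage, width = 0.045, floor_gain = 0.02) {
  xyz <- as.matrix(montage$positions[, c("x", "y", "z")])
  center <- colMeans(xyz[montage$positions$channel %in% montage$occ3, , drop = FALSE])
  d2 <- rowSums(sweep(xyz, 2, center)^2)
  floor_gain + (1 - floor_gain) * exp(-d2 / (2 * width^2))
}
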