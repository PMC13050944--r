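#' Idealized spherical coordinates for the 32-channel 10-10 montage
#'
#' Unit-sphere electrode positions for the 32 scalp sites used throughout the
#' package (Fp1 ... Fp2). The coordinates are the standard 10-10 positions
#' projected onto a best-fit sphere centred in the head; x points to the
#' right ear, y to the nasion, z to the vertex. Distances between these
#' idealized positions drive neighbor interpolation and the spatially
#' correlated noise model.
#'
#' @param labels Optional character vector of channel names to return, in
#'   order. Defaults to the full 32-channel montage.
#' @return A numeric matrix with one row per channel (rownames = labels) and
#'   columns `x`, `y`, `z` on the unit sphere.
#' @examples
#' pos <- montagePositions()
#' stopifnot(nrow(pos) == 32, max(abs(sqrt(rowSums(pos^2)) - 1)) < 1e-6)
#' @export
montagePositions <- function(labels = NULL) {
  tab <- matrix(c(
    -0.289637, 0.954848, -0.066145,
    -0.007350, 0.748698, 0.662870,
    -0.532708, 0.723852, 0.438475,
    -0.764397, 0.633076, -0.122113,
    -0.680050, 0.556637, -0.477165,
    -0.876881, 0.394721, 0.274363,
    -0.361191, 0.438206, 0.823114,
    -0.716923, 0.053494, 0.695097,
    -0.994052, 0.006627, -0.108705,
    -0.881950, -0.327705, 0.338782,
    -0.354740, -0.297909, 0.886233,
    -0.006912, -0.615413, 0.788174,
    -0.542648, -0.624403, 0.561831,
    -0.790576, -0.611792, -0.026457,
    -0.725067, -0.559806, -0.401116,
    -0.301684, -0.949356, 0.087811,
    -0.009476, -0.988982, 0.147734,
    0.287351, -0.953765, 0.088100,
    0.716221, -0.568329, -0.405006,
    0.786525, -0.616948, -0.027441,
    0.545463, -0.618929, 0.565153,
    0.363414, -0.296755, 0.883100,
    0.886373, -0.317979, 0.336502,
    0.993549, 0.018522, -0.111878,
    0.719014, 0.061885, 0.692235,
    -0.006450, 0.073794, 0.997253,
    0.351627, 0.448460, 0.821731,
    0.872466, 0.405998, 0.271971,
    0.676560, 0.558402, -0.480056,
    0.756845, 0.641362, -0.125860,
    0.527401, 0.736183, 0.424127,
    0.272603, 0.959812, -0.066699), ncol = 3, byrow = TRUE)
  rownames(tab) <- c("Fp1", "Fz", "F3", "F7", "F9", "FC5", "FC1", "C3",
                     "T7", "CP5", "CP1", "Pz", "P3", "P7", "P9", "O1",
                     "Oz", "O2", "P10", "P8", "P4", "CP2", "CP6", "T8",
                     "C4", "Cz", "FC2", "FC6", "F10", "F8", "F4", "Fp2")
  colnames(tab) <- c("x", "y", "z")
  if (!is.null(labels)) {
    missing <- setdiff(labels, rownames(tab))
    if (length(missing))
      stop("unknown channel label(s): ", paste(missing, collapse = ", "))
    tab <- tab[labels, , drop = FALSE]
  }
  tab
}

#' Nearest-neighbor structure of a montage
#'
#' For every channel, finds its `k` nearest neighbors by great-circle
#' distance on the idealized sphere. Used by [interpolateBadChannels()],
#' which replaces a bad channel by the inverse-distance-weighted mean of its
#' neighbors.
#'
#' @param positions Channel positions, rows = channels (as from
#'   [montagePositions()]), or a character vector of labels.
#' @param k Number of neighbors per channel (default 3).
#' @return An object of class `channelNeighborhood`: a list with `neighbors`
#'   (channel x k index matrix) and `distances` (channel x k great-circle
#'   distances, radians).
#' @examples
#' nb <- channelNeighbors(montagePositions(), k = 3)
#' @export
channelNeighbors <- function(positions = montagePositions(), k = 3L) {
  if (is.character(positions)) positions <- montagePositions(positions)
  n <- nrow(positions)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k >= n) stop("k must be smaller than the number of channels")
  u <- positions / sqrt(rowSums(positions^2))
  cosang <- tcrossprod(u)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  d <- acos(cosang)
  nb <- matrix(0L, n, k)
  dist <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(d[i, ])
    ord <- ord[ord != i][seq_len(k)]   # a channel is never its own neighbor
    nb[i, ] <- ord
    dist[i, ] <- d[i, ord]
  }
  rownames(nb) <- rownames(dist) <- rownames(positions)
  structure(list(neighbors = nb, distances = dist, labels = rownames(positions)),
            class = "channelNeighborhood")
}
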