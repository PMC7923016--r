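#' Classical multidimensional scaling of populations from allele frequencies
#'
#' Concatenates each population's per-locus allele-frequency vectors (an
#' allele absent from a population contributes frequency 0), computes the
#' Euclidean dissimilarity matrix D between populations, and applies
#' classical (Torgerson) scaling — double centering of -D^2/2 followed by
#' eigendecomposition, with coordinates scaled by the square root of the
#' eigenvalues (delegated to [stats::cmdscale()]). Populations with
#' identical frequency vectors map to identical coordinates. For a
#' deterministic orientation, each component is flipped so that its largest
#' absolute coordinate is positive.
#'
#' @param freq_table a `"ba_freq_table"` covering at least 3 populations.
#' @param dims number of components requested (default 2); truncated with a
#'   warning if fewer positive eigenvalues exist.
#' @return an object of class `"ba_mds"`: list with `coordinates` (matrix,
#'   one row per population, columns `C1`, `C2`, ...), `eigenvalues`,
#'   `distance_matrix` and `goodness` (share of positive inertia captured
#'   by the returned components).
#' @export
classical_mds <- function(freq_table, dims = 2) {
  breeds <- freq_breeds(freq_table)
  if (length(breeds) < 2) stop_validation("MDS needs at least 2 populations (got %d)", length(breeds))
  loci <- unique(freq_table$locus)
  cols <- unlist(lapply(loci, function(ln) {
    al <- sort_c(unique(freq_table$allele[freq_table$locus == ln]))
    paste(ln, al, sep = ".")
  }))
  mat <- matrix(0, nrow = length(breeds), ncol = length(cols),
                dimnames = list(breeds, cols))
  for (i in seq_len(nrow(freq_table))) {
    mat[freq_table$breed[i], paste(freq_table$locus[i], freq_table$allele[i], sep = ".")] <-
      freq_table$freq[i]
  }
  d <- stats::dist(mat)
  fit <- stats::cmdscale(d, k = min(dims, length(breeds) - 1), eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > max(eig) * 1e-12)
  if (npos < dims) {
    warning(sprintf("only %d positive eigenvalue(s); returning %d component(s)", npos, npos),
            call. = FALSE)
  }
  keep <- seq_len(min(dims, max(npos, 1)))
  coords <- fit$points[, keep, drop = FALSE]
  # sign convention: largest-|coordinate| entry of each component positive
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("C", seq_len(ncol(coords)))
  goodness <- sum(eig[keep]) / sum(eig[eig > 0])
  structure(list(coordinates = coords, eigenvalues = eig,
                 distance_matrix = as.matrix(d), goodness = goodness),
            class = "ba_mds")
}

#' @export
print.ba_mds <- function(x, ...) {
  cat(sprintf("<classical MDS> %d populations, %d component(s), %.1f%% of positive inertia\n",
              nrow(x$coordinates), ncol(x$coordinates), 100 * x$goodness))
  print(round(x$coordinates, 4))
  invisible(x)
}
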