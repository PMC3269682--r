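#' Elastic network parameters
#'
#' @param cutoff contact cutoff distance in Angstrom. 7.3 A is the GNM
#'   default used throughout; anisotropic networks typically need a larger
#'   cutoff (see [build_hessian()]).
#' @param gamma uniform harmonic spring constant (energy/A^2); every
#'   contact gets the same spring.
#' @param kT_scale the physical prefactor 3 k_B T / gamma collapsed into a
#'   single reporting scale. All fluctuation outputs are proportional to it;
#'   profiles are typically normalized, so the default of 1 is natural.
#' @return a list of class `enm_params`.
#' @export
enm_params <- function(cutoff = 7.3, gamma = 1, kT_scale = 1) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (kT_scale <= 0) stop("kT_scale must be > 0")
  structure(list(cutoff = cutoff, gamma = gamma, kT_scale = kT_scale),
            class = "enm_params")
}

#' Build the GNM Kirchhoff (contact Laplacian) matrix
#'
#' Off-diagonal element (i, j) is -1 when the pairwise distance is within
#' the cutoff (inclusive), 0 otherwise; the diagonal holds each node's
#' contact count so rows sum exactly to zero. Distances only — the result
#' is invariant to rigid motion of the input coordinates.
#'
#' @param nodes a [node_set()].
#' @param params an [enm_params()]; only `cutoff` is used here (the spring
#'   constant scales the spectrum uniformly and is applied at
#'   decomposition).
#' @return a list of class `kirchhoff`: `matrix` (N x N), `cutoff_used`,
#'   `contact_count` (number of off-diagonal -1 pairs).
#' @export
build_kirchhoff <- function(nodes, params = enm_params()) {
  validate_node_set(nodes)
  d <- as.matrix(stats::dist(nodes$xyz))
  contact <- (d <= params$cutoff)
  diag(contact) <- FALSE
  k <- -1 * contact
  diag(k) <- rowSums(contact)
  dimnames(k) <- NULL
  isolated <- which(rowSums(contact) == 0)
  if (length(isolated) > 0L)
    message("node(s) with zero contacts (graph disconnection): ",
            paste(isolated - 1L, collapse = ", "))
  structure(list(matrix = k, cutoff_used = params$cutoff,
                 contact_count = sum(contact) / 2L),
            class = "kirchhoff")
}

# shared eigen machinery for GNM and ANM: ascending eigenvalues, each
# eigenvector's largest-magnitude entry made positive (first on ties)
.decompose_sym <- function(m, zero_tol) {
  e <- eigen(m, symmetric = TRUE)
  idx <- rev(seq_along(e$values))
  values <- e$values[idx]
  vectors <- e$vectors[, idx, drop = FALSE]
  for (j in seq_len(ncol(vectors))) {
    i <- which.max(abs(vectors[, j]))
    if (vectors[i, j] < 0) vectors[, j] <- -vectors[, j]
  }
  vmax <- max(abs(values))
  n_zero <- if (vmax == 0) length(values) else sum(values < zero_tol * vmax)
  list(values = values, vectors = vectors, n_zero_modes = n_zero)
}

#' Eigendecompose a Kirchhoff matrix
#'
#' Full symmetric eigendecomposition with ascending eigenvalues. The sign
#' of each eigenvector is fixed so its largest-magnitude entry is positive
#' (first such entry on ties), making mode shapes reproducible across
#' solvers. Eigenvalues below `zero_tol` times the largest eigenvalue are
#' counted as zero modes; for a contact graph this count equals the number
#' of connected components.
#'
#' @param k a [build_kirchhoff()] result (or a bare symmetric matrix).
#' @param zero_tol relative tolerance separating graph-theoretic zero modes
#'   from numerical noise.
#' @param params an [enm_params()]; eigenvalues are scaled by `gamma`.
#' @return a list of class `gnm_spectrum`: `values` (ascending),
#'   `vectors` (orthonormal columns), `n_zero_modes`, `n` (nodes).
#' @export
gnm_decompose <- function(k, zero_tol = 1e-8, params = enm_params()) {
  m <- if (inherits(k, "kirchhoff")) k$matrix else as.matrix(k)
  d <- .decompose_sym(m * params$gamma, zero_tol)
  structure(c(d, list(n = nrow(m), zero_tol = zero_tol)),
            class = "gnm_spectrum")
}

# map user-facing 1-based non-rigid mode indices to eigen storage columns
.nonrigid_cols <- function(spec, modes) {
  avail <- length(spec$values) - spec$n_zero_modes
  if (avail < 1L) stop("no non-rigid modes available")
  if (any(modes < 1L))
    stop("rigid mode requested: non-rigid mode indices start at 1")
  if (any(modes > avail))
    stop("mode index beyond available non-rigid modes (", avail, ")")
  spec$n_zero_modes + as.integer(modes)
}

#' Per-node mean-square fluctuation in one mode
#'
#' For non-rigid mode k the mean-square fluctuation of node i is
#' `kT_scale / lambda_k * u_k[i]^2`. The normalized profile (unit sum) is
#' the "normalized distribution of squared fluctuations" plotted for slow
#' modes.
#'
#' @param spec a [gnm_decompose()] spectrum.
#' @param mode_k 1-based non-rigid mode index (1 = slowest).
#' @param params an [enm_params()]; supplies `kT_scale`.
#' @return list with `msf` (per-node, kT_scale units) and `normalized`
#'   (unit-sum profile).
#' @export
mode_fluctuation <- function(spec, mode_k = 1L, params = enm_params()) {
  col <- .nonrigid_cols(spec, mode_k)
  if (length(col) != 1L) stop("mode_k must be a single mode")
  u <- spec$vectors[, col]
  v <- params$kT_scale / spec$values[col] * u^2
  list(msf = v, normalized = v / sum(v))
}

#' Mean-square fluctuations over a mode range
#'
#' Sums [mode_fluctuation()] over the requested non-rigid modes. With
#' `modes = "all"` the result equals `kT_scale` times the diagonal of the
#' Moore-Penrose pseudo-inverse of the Kirchhoff matrix.
#'
#' @param spec a [gnm_decompose()] spectrum.
#' @param modes `"all"`, or an integer vector of 1-based non-rigid mode
#'   indices, or `c(start, count)` given as a 2-element list
#'   `list(start, count)`.
#' @param params an [enm_params()].
#' @return per-node numeric vector.
#' @export
msf <- function(spec, modes = "all", params = enm_params()) {
  modes <- .resolve_modes(spec, modes)
  cols <- .nonrigid_cols(spec, modes)
  u2 <- spec$vectors[, cols, drop = FALSE]^2
  drop(u2 %*% (params$kT_scale / spec$values[cols]))
}

.resolve_modes <- function(spec, modes) {
  avail <- length(spec$values) - spec$n_zero_modes
  if (identical(modes, "all")) return(seq_len(avail))
  if (is.list(modes) && length(modes) == 2L) {
    start <- as.integer(modes[[1]]); count <- as.integer(modes[[2]])
    modes <- seq.int(start, length.out = count)
  }
  modes <- as.integer(modes)
  if (length(modes) == 0L) stop("empty mode range")
  modes
}

#' Cross-correlation map over a mode range
#'
#' Raw covariance between nodes i and j over the chosen non-rigid modes is
#' `sum_k 1/lambda_k * u_k[i] * u_k[j]`; it is normalized by the geometric
#' mean of the two diagonal entries so that values lie in `[-1, 1]` with a
#' unit diagonal. Slow modes carry the functional signal, so the default
#' range is the first 40 non-rigid modes (clipped, with a warning, when
#' fewer are available). Positive values mean in-phase motion, negative
#' anti-phase.
#'
#' @param spec a [gnm_decompose()] spectrum.
#' @param first 1-based index of the first non-rigid mode to include.
#' @param count number of modes (default 40).
#' @return a list of class `cross_correlation`: `matrix` (N x N),
#'   `mode_range = c(first, count_used)`.
#' @export
cross_correlation <- function(spec, first = 1L, count = 40L) {
  avail <- length(spec$values) - spec$n_zero_modes
  first <- as.integer(first); count <- as.integer(count)
  if (first < 1L) stop("first must be >= 1 (non-rigid modes)")
  if (first > avail) stop("first exceeds available non-rigid modes")
  if (first + count - 1L > avail) {
    count <- avail - first + 1L
    warning("mode range clipped to ", count, " available non-rigid modes")
  }
  cols <- .nonrigid_cols(spec, seq.int(first, length.out = count))
  v <- spec$vectors[, cols, drop = FALSE]
  cov <- v %*% (t(v) / spec$values[cols])
  d <- diag(cov)
  zero_var <- d <= 0
  if (any(zero_var)) {
    warning(sum(zero_var), " node(s) with zero variance over the mode ",
            "range; their correlations set to 0")
    d[zero_var] <- 1
  }
  cmat <- cov / sqrt(outer(d, d))
  cmat[zero_var, ] <- 0
  cmat[, zero_var] <- 0
  cmat <- (cmat + t(cmat)) / 2
  diag(cmat) <- 1
  structure(list(matrix = cmat, mode_range = c(first, count)),
            class = "cross_correlation")
}
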