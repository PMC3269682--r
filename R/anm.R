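#' Build the ANM Hessian matrix
#'
#' The anisotropic network model keeps directional information: the second
#' derivative of the pairwise-spring potential at the equilibrium geometry
#' is a 3N x 3N Hessian whose 3x3 off-diagonal block for a contacting pair
#' (i, j) is `-gamma / R_ij^2 * outer(d_ij, d_ij)` with `d_ij` the
#' coordinate difference vector. Diagonal blocks are computed as the
#' negative sums of the off-diagonal blocks in their row, which makes
#' translation invariance (vanishing block row sums) exact in floating
#' point. Node i occupies rows/columns `3i..3i+2` in x, y, z order
#' (1-based: `3(i-1)+1 .. 3(i-1)+3`).
#'
#' The cutoff for the anisotropic network defaults to 13 A rather than the
#' 7.3 A used for the scalar model: a C-alpha network at 7.3 A is often
#' under-constrained in 3D (spurious floppy modes), and 12-15 A is the
#' standard practice for C-alpha ANM.
#'
#' @param nodes a [node_set()].
#' @param params an [enm_params()]; pass `enm_params(cutoff = 13)` (the
#'   ANM default used by the pipeline) or any other cutoff.
#' @return a list of class `hessian`: `matrix` (3N x 3N), `cutoff_used`,
#'   `contact_count`.
#' @export
build_hessian <- function(nodes, params = enm_params(cutoff = 13)) {
  validate_node_set(nodes)
  n <- nodes$n
  xyz <- nodes$xyz
  d <- as.matrix(stats::dist(xyz))
  contact <- (d <= params$cutoff)
  diag(contact) <- FALSE
  pairs <- which(contact & upper.tri(contact), arr.ind = TRUE)
  h <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    dij <- xyz[j, ] - xyz[i, ]
    r2 <- sum(dij^2)
    if (r2 == 0)
      stop("coincident nodes in contact: node indices ", i - 1L, " and ",
           j - 1L, " (zero distance)")
    b <- -(params$gamma / r2) * tcrossprod(dij)
    ri <- (3 * i - 2):(3 * i); rj <- (3 * j - 2):(3 * j)
    h[ri, rj] <- b
    h[rj, ri] <- b
    h[ri, ri] <- h[ri, ri] - b
    h[rj, rj] <- h[rj, rj] - b
  }
  structure(list(matrix = h, cutoff_used = params$cutoff,
                 contact_count = nrow(pairs)),
            class = "hessian")
}

#' Eigendecompose an ANM Hessian
#'
#' Ascending eigenpairs with the same sign convention as [gnm_decompose()].
#' A connected, non-collinear 3D structure has exactly 6 zero (rigid-body)
#' modes — 3 translations and 3 rotations; any other count is reported with
#' a warning since it signals collinear or disconnected geometry.
#'
#' @param h a [build_hessian()] result (or bare symmetric matrix).
#' @param zero_tol relative tolerance for the zero-mode count.
#' @return a list of class `anm_spectrum`: `values`, `vectors`,
#'   `n_zero_modes`, `n` (nodes).
#' @export
anm_decompose <- function(h, zero_tol = 1e-8) {
  m <- if (inherits(h, "hessian")) h$matrix else as.matrix(h)
  d <- .decompose_sym(m, zero_tol)
  if (d$n_zero_modes != 6L)
    warning("expected 6 rigid-body modes, found ", d$n_zero_modes,
            " (collinear or disconnected geometry?)")
  structure(c(d, list(n = nrow(m) %/% 3L, zero_tol = zero_tol)),
            class = "anm_spectrum")
}

#' Displacement field of one anisotropic mode
#'
#' Reshapes the 3N eigenvector of a non-rigid mode into N per-node
#' displacement 3-vectors (unit-normalized in 3N space, as eigenvectors
#' are) plus per-node Euclidean magnitudes — the quantities rendered as
#' cones in mode visualizations, where cone length tracks motion magnitude
#' and orientation the direction.
#'
#' @param spec an [anm_decompose()] spectrum.
#' @param mode 1-based non-rigid mode index (1 = slowest).
#' @return list with `vectors` (N x 3 matrix), `magnitude` (length-N),
#'   `eigenvalue`.
#' @export
mode_vectors <- function(spec, mode = 1L) {
  col <- .nonrigid_cols(spec, mode)
  if (length(col) != 1L) stop("mode must be a single mode")
  v <- matrix(spec$vectors[, col], ncol = 3, byrow = TRUE)
  colnames(v) <- c("x", "y", "z")
  list(vectors = v, magnitude = sqrt(rowSums(v^2)),
       eigenvalue = spec$values[col])
}

#' Export anisotropic modes in NMD format
#'
#' Writes the plain-text NMD format consumed by standard normal-mode
#' viewers: atom names, residue numbers, flattened coordinates, then one
#' `mode` line per requested mode carrying the mode index, a scale factor,
#' and the 3N components. Mode vectors are scaled by `1/sqrt(lambda)` by
#' default (thermal amplitude); `1/lambda` and raw eigenvector scaling are
#' available since visualization conventions differ.
#'
#' @param nodes the [node_set()] the spectrum was computed from.
#' @param spec an [anm_decompose()] spectrum.
#' @param modes integer vector of 1-based non-rigid mode indices; an empty
#'   vector writes a header-only file with a warning.
#' @param path output file path.
#' @param scaling one of `"inv_sqrt"`, `"inv"`, `"raw"`.
#' @param name title recorded in the file.
#' @return `path`, invisibly.
#' @export
write_nmd <- function(nodes, spec, modes = 1L, path,
                      scaling = c("inv_sqrt", "inv", "raw"),
                      name = "enmodes_anm") {
  validate_node_set(nodes)
  scaling <- match.arg(scaling)
  fmt <- function(x) paste(sprintf("%.9f", x), collapse = " ")
  lines <- c(
    paste("nmd", name),
    paste("names", paste(rep("CA", nodes$n), collapse = " ")),
    paste("resnames", paste(nodes$resid, collapse = " ")),
    paste("chids", paste(nodes$chain, collapse = " ")),
    paste("resids", paste(nodes$resno, collapse = " ")),
    paste("coordinates", fmt(t(nodes$xyz))))
  if (length(modes) == 0L) {
    warning("empty mode list: writing header-only NMD file")
  } else {
    for (m in modes) {
      mv <- mode_vectors(spec, m)
      scale <- switch(scaling,
                      inv_sqrt = 1 / sqrt(mv$eigenvalue),
                      inv = 1 / mv$eigenvalue,
                      raw = 1)
      lines <- c(lines,
                 paste("mode", m, sprintf("%.6f", scale), fmt(t(mv$vectors))))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an NMD file written by [write_nmd()]
#'
#' @param path NMD file path.
#' @return list with `coordinates` (N x 3), `resids`, and `modes`: a list
#'   of `list(index, scale, vectors)` entries.
#' @export
read_nmd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  get1 <- function(key) {
    ln <- lines[startsWith(lines, paste0(key, " "))]
    if (length(ln) == 0L) return(NULL)
    strsplit(sub(paste0("^", key, " "), "", ln[1]), " ")[[1]]
  }
  coords <- as.numeric(get1("coordinates"))
  out <- list(coordinates = matrix(coords, ncol = 3, byrow = TRUE),
              resids = as.integer(get1("resids")), modes = list())
  for (ln in lines[startsWith(lines, "mode ")]) {
    parts <- strsplit(ln, " ")[[1]]
    out$modes[[length(out$modes) + 1L]] <-
      list(index = as.integer(parts[2]), scale = as.numeric(parts[3]),
           vectors = matrix(as.numeric(parts[-(1:3)]), ncol = 3,
                            byrow = TRUE))
  }
  out
}
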