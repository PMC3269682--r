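#' Pair the nodes of two structures by residue identity
#'
#' Conformations of the same protein (a monomer and the same domain inside
#' a complex, say) are paired by the (chain, resSeq, iCode) key; residues
#' present in only one structure are excluded and reported. No sequence
#' alignment is attempted — numbering is assumed consistent.
#'
#' @param ref,mov two [node_set()] objects.
#' @return list with `pairs` (two-column matrix of 0-based node indices,
#'   ref then mov, in ref order), `unmatched_ref`, `unmatched_mov`
#'   (0-based indices).
#' @export
match_by_residue <- function(ref, mov) {
  validate_node_set(ref); validate_node_set(mov)
  key <- function(x) paste(x$chain, x$resno, x$insert, sep = "\r")
  kr <- key(ref); km <- key(mov)
  m <- match(kr, km)
  got <- !is.na(m)
  if (!any(got))
    stop("no residues in common between the two structures")
  pairs <- cbind(ref = which(got) - 1L, mov = m[got] - 1L)
  list(pairs = pairs,
       unmatched_ref = which(!got) - 1L,
       unmatched_mov = setdiff(seq_len(mov$n), m[got]) - 1L)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimize the RMSD of the
#' mobile coordinates onto the reference over a fit selection, via SVD of
#' the covariance matrix with the determinant correction that excludes
#' reflections. The transform is then applied to all matched pairs, so
#' regions excluded from the fit still get per-residue deviations — that is
#' how deformation localizes when fitting on a rigid core.
#'
#' @param ref_xyz,mov_xyz matched coordinate matrices (same row count).
#' @param fit row indices (1-based) used for the fit; default all rows.
#' @return a list of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (so that `mov %*% rotation + translation` superposes),
#'   `rmsd` (over the fit selection), `per_residue_deviation` (all rows),
#'   `fit_selection`, `transformed` (mov after the transform).
#' @export
kabsch_superpose <- function(ref_xyz, mov_xyz, fit = NULL) {
  ref_xyz <- as.matrix(ref_xyz); mov_xyz <- as.matrix(mov_xyz)
  if (!all(dim(ref_xyz) == dim(mov_xyz)))
    stop("coordinate sets must have identical dimensions")
  n <- nrow(ref_xyz)
  if (is.null(fit)) fit <- seq_len(n)
  if (length(fit) < 3L)
    stop("fit selection needs at least 3 pairs")
  a <- mov_xyz[fit, , drop = FALSE]
  b <- ref_xyz[fit, , drop = FALSE]
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  sv <- svd(a0)$d
  if (sum(sv > 1e-9 * max(sv, 1e-300)) < 2L)
    stop("degenerate (collinear) fit selection")
  h <- crossprod(a0, b0)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  trans <- unname(cb - drop(ca %*% rot))
  transformed <- sweep(mov_xyz %*% rot, 2, trans, "+")
  dev <- sqrt(rowSums((transformed - ref_xyz)^2))
  structure(list(rotation = rot, translation = trans,
                 rmsd = sqrt(mean(dev[fit]^2)),
                 per_residue_deviation = dev,
                 fit_selection = fit, transformed = transformed),
            class = "superposition")
}

#' Superpose one structure onto another by residue pairing
#'
#' Convenience wrapper: [match_by_residue()], then [kabsch_superpose()].
#' With `fit = "trimmed"` the fit anchors on the rigid core: one full fit,
#' then the worst 10% of pairs by deviation are dropped and the fit is
#' repeated once. Anchoring on the core is what lets genuine deformations
#' (a bent helix, a displaced loop) stand out in the per-residue
#' deviations instead of being averaged into the global fit.
#'
#' @param ref,mov [node_set()] objects (mov is superposed onto ref).
#' @param fit `"all"`, `"trimmed"`, or an integer vector of pair row
#'   indices (1-based into the matched pair list).
#' @param trim_fraction fraction of worst pairs dropped in trimmed mode.
#' @return the [kabsch_superpose()] result, with `pairs` and `matching`
#'   added.
#' @export
superpose_nodes <- function(ref, mov, fit = "all", trim_fraction = 0.10) {
  matching <- match_by_residue(ref, mov)
  p <- matching$pairs
  rxyz <- ref$xyz[p[, "ref"] + 1L, , drop = FALSE]
  mxyz <- mov$xyz[p[, "mov"] + 1L, , drop = FALSE]
  if (identical(fit, "all")) {
    res <- kabsch_superpose(rxyz, mxyz)
  } else if (identical(fit, "trimmed")) {
    res <- kabsch_superpose(rxyz, mxyz)
    keep <- order(res$per_residue_deviation)[
      seq_len(max(3L, floor(nrow(p) * (1 - trim_fraction))))]
    res <- kabsch_superpose(rxyz, mxyz, fit = sort(keep))
  } else {
    res <- kabsch_superpose(rxyz, mxyz, fit = as.integer(fit))
  }
  res$pairs <- p
  res$matching <- matching
  res
}

#' Bend angle of a helix from two half-axes
#'
#' Splits a helix range at a given node, fits an axis to each half, and
#' returns the angle between the two axes in degrees. A straight helix
#' reads near 0; a long central helix bending under binding-partner load
#' reads as the bend magnitude.
#'
#' The axis of each half is the null principal direction of its
#' second-difference vectors: for an ideal helix the rise cancels exactly
#' in `p[i+2] - 2 p[i+1] + p[i]`, leaving vectors that lie exactly in the
#' plane perpendicular to the axis, so the estimator is unbiased even for
#' fragments covering partial turns (a plain principal-component fit of
#' the coordinates tilts by several degrees on short fragments). When the
#' second differences are degenerate (a straight or planar trace), the
#' dominant principal direction of the centroid-centred coordinates is
#' used instead. Axes are sign-aligned to the N-to-C direction. Each half
#' needs at least 4 residues. The measure is invariant under rigid
#' transformation and uniform scaling of the coordinates.
#'
#' @param nodes a [node_set()].
#' @param helix_range `c(start, end)` node indices (0-based, inclusive).
#' @param split node index inside the range; the first half is
#'   `start..split`, the second `split+1..end`.
#' @return bend angle in degrees, in `[0, 180)`.
#' @export
helix_bend_angle <- function(nodes, helix_range, split) {
  validate_node_set(nodes)
  start <- as.integer(helix_range[1]); end <- as.integer(helix_range[2])
  split <- as.integer(split)
  if (start < 0L || end > nodes$n - 1L || start >= end)
    stop("invalid helix range")
  if (split < start || split >= end) stop("split must lie inside the range")
  h1 <- (start:split) + 1L
  h2 <- ((split + 1L):end) + 1L
  if (length(h1) < 4L || length(h2) < 4L)
    stop("each half of the split range needs at least 4 nodes")
  axis_of <- function(rows) {
    xyz <- nodes$xyz[rows, , drop = FALSE]
    sd2 <- diff(diff(xyz))
    s <- svd(sd2)
    if (s$d[1] <= 0 || s$d[2] < 1e-8 * s$d[1]) {
      # straight or planar trace: fall back to the dominant principal
      # direction of the centroid-centred coordinates
      c0 <- sweep(xyz, 2, colMeans(xyz))
      v <- svd(c0)$v[, 1]
    } else {
      v <- s$v[, 3]
    }
    nc <- xyz[nrow(xyz), ] - xyz[1, ]
    if (sum(v * nc) < 0) v <- -v
    v
  }
  a1 <- axis_of(h1); a2 <- axis_of(h2)
  cosang <- max(-1, min(1, sum(a1 * a2)))
  ang <- acos(cosang) * 180 / pi
  if (ang >= 180) ang <- 0
  ang
}
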