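#' Generate a synthetic C-alpha structure with known topology
#'
#' Stand-ins for crystal structures, with geometry simple enough that the
#' elastic-network results have closed forms or constructed ground truth:
#'
#' * `chain` — straight line of `n` nodes, `spacing` apart.
#' * `ring` — `n` nodes equally spaced on a circle with chord length
#'   `spacing`; its contact Laplacian is circulant, so the spectrum has a
#'   closed form.
#' * `helix` — ideal alpha-helix: `rise` per residue along z, `twist`
#'   degrees per residue, C-alpha `radius` from the axis. The defaults
#'   (1.5 A, 100 deg, 2.3 A) give the canonical ~3.8 A consecutive
#'   C-alpha distance.
#' * `bundle` — `n_helices` ideal helices of `n` residues each, axes on a
#'   circle of radius `bundle_radius`, alternating up/down (antiparallel),
#'   numbered sequentially — a minimal helix-bundle domain.
#' * `dumbbell` — two compact FCC-packed blobs of `cluster_n` nodes joined
#'   by a thin `linker_n`-node strand at 3.8 A spacing: a two-domain
#'   system whose slow mode hinges at the linker. Ground-truth domain
#'   annotation and linker range are attached.
#' * `gapped_chain` — a chain whose residue numbering jumps by `gap_size`
#'   after the `gap_at`-th residue while the trace stays continuous,
#'   emulating a disordered segment absent from the deposited coordinates.
#'
#' Gaussian coordinate noise of sd `noise_sd` is added after ideal
#' construction. Output is deterministic given `seed` (the caller's RNG
#' state is left untouched).
#'
#' @param kind one of `"chain"`, `"ring"`, `"helix"`, `"bundle"`,
#'   `"dumbbell"`, `"gapped_chain"`.
#' @param n residues per chain/ring/helix (per helix for `bundle`).
#' @param spacing consecutive-node distance in Angstrom (chain/ring).
#' @param rise,twist,radius helix geometry (Angstrom, degrees, Angstrom).
#' @param n_helices,bundle_radius bundle layout.
#' @param cluster_n,linker_n dumbbell blob and linker sizes.
#' @param gap_at,gap_size gapped-chain: numbering jumps by `gap_size`
#'   after the `gap_at`-th node.
#' @param noise_sd Gaussian noise sd in Angstrom.
#' @param seed integer RNG seed for the noise.
#' @return a [node_set()]; dumbbells carry attributes `annotation` (a
#'   domain annotation with segments `A`, `linker`, `B`) and
#'   `linker_range` (0-based inclusive node range).
#' @export
synthetic_structure <- function(kind = c("chain", "ring", "helix", "bundle",
                                         "dumbbell", "gapped_chain"),
                                n = 20L, spacing = 3.8, rise = 1.5,
                                twist = 100, radius = 2.3,
                                n_helices = 4L, bundle_radius = 4.5,
                                cluster_n = 20L, linker_n = 4L,
                                gap_at = NULL, gap_size = 10L,
                                noise_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  n <- as.integer(n)
  if (n < 2L) stop("n must be >= 2")
  if (spacing <= 0 || rise <= 0 || radius <= 0)
    stop("spacing, rise and radius must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  helix_xyz <- function(nn, phase = 0, flip = FALSE) {
    i <- seq_len(nn) - 1
    th <- (phase + i * twist) * pi / 180
    z <- i * rise
    if (flip) z <- rev(z)
    cbind(radius * cos(th), radius * sin(th), z)
  }

  ann <- NULL; linker_range <- NULL
  if (kind == "chain" || kind == "gapped_chain") {
    xyz <- cbind((seq_len(n) - 1) * spacing, 0, 0)
    resno <- seq_len(n)
    if (kind == "gapped_chain") {
      if (is.null(gap_at)) gap_at <- n %/% 2L
      gap_at <- as.integer(gap_at)
      if (gap_at < 1L || gap_at >= n) stop("gap_at must be in 1..n-1")
      resno[(gap_at + 1L):n] <- resno[(gap_at + 1L):n] + as.integer(gap_size)
    }
  } else if (kind == "ring") {
    r <- spacing / (2 * sin(pi / n))
    th <- 2 * pi * (seq_len(n) - 1) / n
    xyz <- cbind(r * cos(th), r * sin(th), 0)
    resno <- seq_len(n)
  } else if (kind == "helix") {
    xyz <- helix_xyz(n)
    resno <- seq_len(n)
  } else if (kind == "bundle") {
    n_helices <- as.integer(n_helices)
    if (n_helices < 2L) stop("a bundle needs >= 2 helices")
    xyz <- NULL
    for (k in seq_len(n_helices)) {
      ang <- 2 * pi * (k - 1) / n_helices
      off <- c(bundle_radius * cos(ang), bundle_radius * sin(ang), 0)
      h <- helix_xyz(n, phase = 37 * k, flip = (k %% 2L == 0L))
      xyz <- rbind(xyz, sweep(h, 2, off, "+"))
    }
    resno <- seq_len(n * n_helices)
  } else if (kind == "dumbbell") {
    cluster_n <- as.integer(cluster_n); linker_n <- as.integer(linker_n)
    if (cluster_n < 2L || linker_n < 1L)
      stop("dumbbell needs cluster_n >= 2 and linker_n >= 1")
    blob <- .fcc_blob(cluster_n, nn_dist = 3.8)
    a <- blob[order(blob[, 1]), , drop = FALSE]
    pa <- a[nrow(a), ]                     # A's extreme node anchors the linker
    link <- cbind(pa[1] + 3.8 * seq_len(linker_n), pa[2], pa[3])
    b <- blob[order(blob[, 1]), , drop = FALSE]
    qb <- b[1, ]                           # B's extreme node continues the strand
    tail_pt <- c(pa[1] + 3.8 * (linker_n + 1L), pa[2], pa[3])
    b <- sweep(b, 2, qb - tail_pt, "-")
    xyz <- rbind(a, link, b)
    nA <- cluster_n; nL <- linker_n
    resno <- seq_len(nrow(xyz))
    ann <- data.frame(label = c("A", "linker", "B"),
                      start = c(0L, nA, nA + nL),
                      end = c(nA - 1L, nA + nL - 1L, nA + nL + cluster_n - 1L),
                      stringsAsFactors = FALSE)
    class(ann) <- c("domain_annotation", "data.frame")
    linker_range <- c(nA, nA + nL - 1L)
  }

  if (noise_sd > 0) {
    xyz <- xyz + .with_seed(seed, stats::rnorm(length(xyz), sd = noise_sd))
  }
  nodes <- node_set(xyz, resno = resno, chain = "A", resid = "ALA")
  if (!is.null(ann)) attr(nodes, "annotation") <- ann
  if (!is.null(linker_range)) attr(nodes, "linker_range") <- linker_range
  attr(nodes, "kind") <- kind
  nodes
}

# compact FCC-lattice blob: the m lattice points nearest the origin, with
# nearest-neighbour distance nn_dist
.fcc_blob <- function(m, nn_dist = 3.8) {
  a <- nn_dist * sqrt(2)           # cubic lattice constant
  r <- 3L
  g <- expand.grid(i = -r:r, j = -r:r, k = -r:r)
  pts <- NULL
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5))
  for (b in seq_len(4L))
    pts <- rbind(pts, a * (as.matrix(g) + matrix(basis[b, ], nrow(g), 3,
                                                 byrow = TRUE)))
  d2 <- rowSums(pts^2)
  pts[order(d2)[seq_len(m)], , drop = FALSE]
}

# evaluate expr with a fixed seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
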