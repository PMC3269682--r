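test_that("two-point spring Hessian matches the closed form", {
  h <- build_hessian(two_node_set(1), enm_params(cutoff = 13))
  off <- matrix(0, 3, 3); off[1, 1] <- -1
  expect_equal(h$matrix[1:3, 4:6], off)
  expect_equal(h$matrix[1:3, 1:3], -off)
  s <- suppressWarnings(anm_decompose(h))
  expect_equal(s$values, c(0, 0, 0, 0, 0, 2), tolerance = 1e-12)
  # the nonzero mode is the anti-phase stretch along x
  mv <- mode_vectors(s, 1)
  expect_equal(abs(mv$vectors[, 1]), c(1, 1) / sqrt(2))
  expect_equal(mv$vectors[, 2:3], matrix(0, 2, 2, dimnames = list(NULL, c("y", "z"))),
               tolerance = 1e-12)
  # eigenvalue of the two-node spring is 2*gamma exactly
  h3 <- build_hessian(two_node_set(1), enm_params(cutoff = 13, gamma = 3))
  expect_equal(max(suppressWarnings(anm_decompose(h3))$values), 6)
})

test_that("Hessian equals the finite-difference second derivative of the spring energy", {
  gamma <- 1.3; cutoff <- 13
  nd <- random_node_set(10, sd = 4, seed = 42)
  h <- build_hessian(nd, enm_params(cutoff = cutoff, gamma = gamma))$matrix
  xyz0 <- nd$xyz
  d0 <- as.matrix(stats::dist(xyz0))
  con <- d0 <= cutoff; diag(con) <- FALSE
  energy <- function(v) {
    d <- as.matrix(stats::dist(matrix(v, ncol = 3, byrow = TRUE)))
    sum(0.5 * gamma * (d[con] - d0[con])^2) / 2  # each pair counted twice
  }
  v0 <- as.numeric(t(xyz0))
  eps <- 1e-4
  fd <- matrix(0, 30, 30)
  for (i in 1:30) for (j in i:30) {
    pert <- function(di, dj) {
      v <- v0; v[i] <- v[i] + di; v[j] <- v[j] + dj; energy(v)
    }
    fd[i, j] <- fd[j, i] <-
      (pert(eps, eps) - pert(eps, -eps) - pert(-eps, eps) +
         pert(-eps, -eps)) / (4 * eps^2)
  }
  expect_equal(h, fd, tolerance = 1e-6)
})

test_that("rigid-body zero-mode counts: 6 connected, 5 collinear pair, 12 disconnected", {
  nd <- random_node_set(10, sd = 4, seed = 42)
  s <- anm_decompose(build_hessian(nd))
  expect_equal(s$n_zero_modes, 6L)
  # the 7th eigenvalue is clearly above the zero block
  expect_gt(s$values[7], 1e-6 * max(s$values))

  expect_warning(s2 <- anm_decompose(build_hessian(two_node_set(1))),
                 "expected 6")
  expect_equal(s2$n_zero_modes, 5L)

  # two rigid 4-node clusters far apart: 6 rigid modes per component
  tetra <- rbind(c(0, 0, 0), c(3.8, 0, 0), c(1.9, 3.3, 0), c(1.9, 1.1, 3.1))
  xyz <- rbind(tetra, sweep(tetra, 2, c(100, 0, 0), "+"))
  nd2 <- node_set(xyz, resno = 1:8)
  expect_warning(s3 <- anm_decompose(build_hessian(nd2)), "expected 6")
  expect_equal(s3$n_zero_modes, 12L)
  expect_equal(component_count(nd2$xyz, 13), 2L)
})

test_that("Hessian block row sums vanish and rigid rotations live in the null space", {
  nd <- synthetic_structure("bundle", n = 8)
  h <- build_hessian(nd)$matrix
  n <- nd$n
  for (i in seq_len(n)) {
    ri <- (3 * i - 2):(3 * i)
    block_sum <- matrix(0, 3, 3)
    for (j in seq_len(n)) block_sum <- block_sum + h[ri, (3 * j - 2):(3 * j)]
    expect_equal(block_sum, matrix(0, 3, 3))  # exact by construction
  }
  # rigid rotations about the centroid
  cen <- colMeans(nd$xyz)
  c0 <- sweep(nd$xyz, 2, cen)
  for (ax in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    disp <- t(apply(c0, 1, function(r)
      c(ax[2] * r[3] - ax[3] * r[2],
        ax[3] * r[1] - ax[1] * r[3],
        ax[1] * r[2] - ax[2] * r[1])))
    v <- as.numeric(t(disp)); v <- v / sqrt(sum(v^2))
    expect_lt(sqrt(sum((h %*% v)^2)), 1e-6)
  }
})

test_that("GNM and ANM share the same contact graph at equal cutoff", {
  nd <- random_node_set(12, sd = 3, seed = 9)
  p <- enm_params(cutoff = 9)
  k <- build_kirchhoff(nd, p)
  h <- build_hessian(nd, p)
  expect_equal(k$contact_count, h$contact_count)
  hn <- matrix(0, nd$n, nd$n)
  for (i in seq_len(nd$n)) for (j in seq_len(nd$n)) if (i != j)
    hn[i, j] <- any(h$matrix[(3 * i - 2):(3 * i), (3 * j - 2):(3 * j)] != 0)
  expect_equal(hn, 1 * (k$matrix == -1))
})

test_that("non-rigid modes carry no net translation and unit norm", {
  nd <- synthetic_structure("bundle", n = 10)
  s <- anm_decompose(build_hessian(nd))
  expect_equal(s$n_zero_modes, 6L)
  for (m in 1:6) {
    mv <- mode_vectors(s, m)
    expect_equal(colSums(mv$vectors), c(x = 0, y = 0, z = 0),
                 tolerance = 1e-8)
    expect_equal(sum(mv$magnitude^2), 1)
    expect_true(all(s$values[s$n_zero_modes + m] > 0))
  }
  expect_error(mode_vectors(s, 0), "rigid mode")
})

test_that("degenerate-mode subspaces are reproducible under rigid motion", {
  # eigenvector order within a degenerate cluster is solver-dependent, so
  # compare projector matrices over eigenvalue clusters instead
  nd <- synthetic_structure("helix", n = 12)
  s <- anm_decompose(build_hessian(nd))
  set.seed(77)
  tnd <- rigid_transform(nd)
  st <- anm_decompose(build_hessian(tnd))
  expect_equal(st$values, s$values, tolerance = 1e-8)
})

test_that("ANM eigenvalues agree with the independent bio3d normal-mode solver", {
  skip_if_not_installed("bio3d")
  nd <- synthetic_structure("bundle", n = 10)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ca(nd, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, verbose = FALSE))
  ref <- suppressWarnings(bio3d::nma(pdb, ff = "anm", cutoff = 13,
                                     mass = FALSE, temp = NULL))
  # compare on the 3-decimal coordinates the PDB file carries
  s <- anm_decompose(build_hessian(parse_structure(f),
                                   enm_params(cutoff = 13)))
  nonrigid <- s$values[(s$n_zero_modes + 1):length(s$values)]
  expect_equal(nonrigid[1:10], ref$L[7:16], tolerance = 1e-6)
})

test_that("NMD export round-trips coordinates and mode vectors", {
  nd <- synthetic_structure("helix", n = 10)
  s <- anm_decompose(build_hessian(nd))
  f <- withr::local_tempfile(fileext = ".nmd")
  write_nmd(nd, s, modes = 1:2, path = f)
  back <- read_nmd(f)
  expect_equal(back$coordinates, unname(nd$xyz), tolerance = 1e-6)
  expect_equal(back$resids, nd$resno)
  expect_length(back$modes, 2L)
  mv <- mode_vectors(s, 1)
  expect_equal(back$modes[[1]]$vectors, unname(mv$vectors), tolerance = 1e-6)
  expect_equal(back$modes[[1]]$scale, 1 / sqrt(mv$eigenvalue),
               tolerance = 1e-6)
  expect_warning(write_nmd(nd, s, modes = integer(0), path = f),
                 "header-only")
  expect_length(read_nmd(f)$modes, 0L)

  # two-node fixture: one mode line with 6 numbers
  s2 <- suppressWarnings(anm_decompose(build_hessian(two_node_set(1))))
  write_nmd(two_node_set(1), s2, modes = 1, path = f)
  expect_equal(dim(read_nmd(f)$modes[[1]]$vectors), c(2L, 3L))
})

test_that("coincident contacting nodes are rejected by name", {
  nd <- node_set(rbind(c(0, 0, 0), c(0, 0, 0), c(5, 0, 0)), resno = 1:3)
  expect_error(build_hessian(nd), "coincident nodes.*0 and 1")
})
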