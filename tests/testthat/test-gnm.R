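test_that("Kirchhoff matrix follows the contact rule with exact zero row sums", {
  # inclusive cutoff: contact at exactly 3.8 A
  k <- build_kirchhoff(two_node_set(3.8))
  expect_equal(k$matrix, rbind(c(1, -1), c(-1, 1)))
  expect_equal(k$contact_count, 1)

  # beyond cutoff: empty graph (isolated nodes are reported, not an error)
  expect_message(k0 <- build_kirchhoff(two_node_set(8.0)),
                 "zero contacts")
  expect_equal(k0$matrix, matrix(0, 2, 2))

  # 20-node ring with exactly 2 neighbours each, against a brute-force
  # pair enumeration
  ring <- synthetic_structure("ring", n = 20, spacing = 3.8)
  cutoff <- 5.0  # between the 1st (3.8) and 2nd neighbour chord
  kr <- build_kirchhoff(ring, enm_params(cutoff = cutoff))
  brute <- 0
  for (i in 1:19) for (j in (i + 1):20)
    if (sqrt(sum((ring$xyz[i, ] - ring$xyz[j, ])^2)) <= cutoff)
      brute <- brute + 1
  expect_equal(kr$contact_count, brute)
  expect_equal(unname(diag(kr$matrix)), rep(2, 20))
  expect_true(all(rowSums(kr$matrix) == 0))
})

test_that("spectrum: ascending eigenvalues, fixed signs, ring closed form", {
  s2 <- gnm_decompose(build_kirchhoff(two_node_set(3.8)))
  expect_equal(s2$values, c(0, 2))
  expect_equal(abs(s2$vectors[, 2]), c(1, 1) / sqrt(2))
  # sign convention: largest-magnitude entry positive
  expect_true(all(apply(s2$vectors, 2, function(u) u[which.max(abs(u))] > 0)))

  # nearest-neighbour ring eigenvalues match the circulant closed form
  n <- 24
  ring <- synthetic_structure("ring", n = n)
  s <- gnm_decompose(build_kirchhoff(ring, enm_params(cutoff = 4)))
  closed <- sort(2 - 2 * cos(2 * pi * (0:(n - 1)) / n))
  expect_equal(s$values, closed, tolerance = 1e-8)
  expect_equal(s$n_zero_modes, 1L)

  # orthonormality
  g <- crossprod(s$vectors)
  expect_lt(max(abs(g - diag(n))), 1e-8)
})

test_that("zero-mode count equals the connected-component count", {
  # two separated rings -> 2 components
  r1 <- synthetic_structure("ring", n = 10)
  r2 <- synthetic_structure("ring", n = 10)
  xyz <- rbind(r1$xyz, sweep(r2$xyz, 2, c(100, 0, 0), "+"))
  nd <- node_set(xyz, resno = seq_len(20))
  s <- gnm_decompose(build_kirchhoff(nd))
  expect_equal(s$n_zero_modes, 2L)

  # random fragmented structures vs the igraph traversal oracle
  for (seed in 1:5) {
    rnd <- random_node_set(25, sd = 8, seed = seed)
    s <- gnm_decompose(build_kirchhoff(rnd))
    expect_equal(s$n_zero_modes, component_count(rnd$xyz, 7.3))
  }
})

test_that("per-mode fluctuations follow the eigen decomposition", {
  s2 <- gnm_decompose(build_kirchhoff(two_node_set(3.8)))
  mf <- mode_fluctuation(s2, 1)
  expect_equal(mf$msf, c(0.25, 0.25))
  expect_equal(sum(mf$normalized), 1)
  expect_error(mode_fluctuation(s2, 0), "rigid mode")

  # ring symmetry: slowest-mode profile equal at all nodes
  ring <- synthetic_structure("ring", n = 30)
  s <- gnm_decompose(build_kirchhoff(ring, enm_params(cutoff = 4)))
  # slowest ring mode is doubly degenerate; profile uniformity holds for
  # the degenerate pair summed
  pair <- mode_fluctuation(s, 1)$msf + mode_fluctuation(s, 2)$msf
  expect_lt(diff(range(pair)), 1e-8)
})

test_that("msf over all modes equals the pseudo-inverse diagonal", {
  nd <- random_node_set(15, sd = 3, seed = 3)
  k <- build_kirchhoff(nd)
  expect_equal(component_count(nd$xyz, 7.3), 1L)  # fixture is connected
  s <- gnm_decompose(k)
  expect_equal(msf(s, "all"), diag(pinv_oracle(k$matrix)), tolerance = 1e-8)

  # kT_scale scales linearly; monotone growth with mode count
  expect_equal(msf(s, "all", enm_params(kT_scale = 2.5)),
               2.5 * msf(s, "all"))
  prev <- rep(0, nd$n)
  for (m in 1:5) {
    cur <- msf(s, seq_len(m))
    expect_true(all(cur >= prev - 1e-14))
    prev <- cur
  }
  expect_error(msf(s, integer(0)), "empty")
})

test_that("cross-correlation is a normalized map matching the pseudo-inverse", {
  s2 <- gnm_decompose(build_kirchhoff(two_node_set(3.8)))
  cc2 <- suppressWarnings(cross_correlation(s2, count = 40))
  expect_equal(cc2$matrix[1, 2], -1)

  nd <- random_node_set(15, sd = 3, seed = 3)
  k <- build_kirchhoff(nd)
  s <- gnm_decompose(k)
  cc <- cross_correlation(s, count = nd$n - 1)
  p <- pinv_oracle(k$matrix)
  ref <- p / sqrt(outer(diag(p), diag(p)))
  expect_equal(cc$matrix, ref, tolerance = 1e-8)
  expect_equal(cc$matrix, t(cc$matrix))
  expect_equal(unname(diag(cc$matrix)), rep(1, nd$n))
  expect_true(all(abs(cc$matrix) <= 1 + 1e-12))

  # clipping warns and records the effective range
  expect_warning(ccl <- cross_correlation(s, count = 40), "clipped")
  expect_equal(ccl$mode_range, c(1, 14))
})

test_that("GNM outputs are invariant under rigid motion of the input", {
  nd <- synthetic_structure("dumbbell")
  s <- gnm_decompose(build_kirchhoff(nd))
  ref_msf <- msf(s, "all")
  ref_cc <- cross_correlation(s, count = 10)$matrix
  set.seed(202)
  for (i in 1:10) {
    tnd <- rigid_transform(nd)
    st <- gnm_decompose(build_kirchhoff(tnd))
    expect_equal(st$values, s$values, tolerance = 1e-10)
    expect_equal(msf(st, "all"), ref_msf, tolerance = 1e-8)
    expect_equal(cross_correlation(st, count = 10)$matrix, ref_cc,
                 tolerance = 1e-8)
  }
})

test_that("fluctuation profile agrees with the independent bio3d GNM", {
  skip_if_not_installed("bio3d")
  nd <- synthetic_structure("dumbbell")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_ca(nd, f)
  pdb <- suppressWarnings(bio3d::read.pdb(f, verbose = FALSE))
  ref <- suppressWarnings(bio3d::gnm(pdb, cutoff = 7.3))
  ours <- msf(gnm_decompose(build_kirchhoff(nd)), "all")
  # scales differ (temperature prefactor); shapes must match
  expect_equal(ours / sum(ours), ref$fluctuations / sum(ref$fluctuations),
               tolerance = 1e-6)
})
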