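# shared fixtures: tiny PDB texts, rigid transforms, independent oracles

pdb_atom_line <- function(serial, resno, x, y, z, name = "CA", alt = " ",
                          chain = "A", occ = 1.00, resid = "ALA",
                          record = "ATOM") {
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
          record, serial, sprintf(" %-3s", name), alt, resid, chain,
          resno, x, y, z, occ, 0.0)
}

two_residue_pdb <- function() {
  paste(c(pdb_atom_line(1, 1, 0, 0, 0),
          pdb_atom_line(2, 2, 3.8, 0, 0),
          "END"), collapse = "\n")
}

# random proper rotation + translation applied to a node set
rigid_transform <- function(nodes) {
  m <- matrix(rnorm(9), 3)
  q <- qr.Q(qr(m))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  t0 <- rnorm(3, sd = 20)
  nodes$xyz <- sweep(nodes$xyz %*% q, 2, t0, "+")
  nodes
}

# independent connected-component count via igraph traversal
component_count <- function(xyz, cutoff) {
  d <- as.matrix(stats::dist(xyz))
  adj <- (d <= cutoff)
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::components(g)$no
}

# independent pseudo-inverse oracle (SVD route, not the eigen route the
# package uses)
pinv_oracle <- function(m) MASS::ginv(m, tol = 1e-10)

two_node_set <- function(d = 1) {
  node_set(rbind(c(0, 0, 0), c(d, 0, 0)), resno = 1:2)
}

random_node_set <- function(n, sd = 4, seed = 1) {
  xyz <- enmodes:::.with_seed(seed, matrix(rnorm(3 * n, sd = sd), n))
  node_set(xyz, resno = seq_len(n))
}

ideal_helix_xyz <- function(n, rise = 1.5, twist = 100, radius = 2.3) {
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180
  cbind(radius * cos(th), radius * sin(th), i * rise)
}

rot_x <- function(deg) {
  th <- deg * pi / 180
  rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
}
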