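#' Construct a C-alpha node set
#'
#' A `node_set` is the coarse-grained representation every analysis in this
#' package operates on: one node per residue, carrying its C-alpha position,
#' the author-assigned residue number (which may have gaps), an insertion
#' code, chain identifier and 3-letter residue name. Node indices are always
#' the contiguous integers `0..N-1` in storage order.
#'
#' @param xyz numeric N x 3 matrix of C-alpha coordinates in Angstrom.
#' @param resno integer vector of author residue numbers (gaps allowed).
#' @param chain character vector of chain identifiers (recycled if length 1).
#' @param resid character vector of 3-letter residue names (recycled).
#' @param insert character vector of insertion codes, `""` if none (recycled).
#'
#' @return An object of class `node_set`: a list with elements `xyz`,
#'   `node` (0-based contiguous indices), `resno`, `insert`, `chain`,
#'   `resid`, and `n`.
#' @export
node_set <- function(xyz, resno, chain = "A", resid = "ALA", insert = "") {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L)
    stop("xyz must have 3 columns (x, y, z)")
  n <- nrow(xyz)
  if (n < 2L)
    stop("a node set needs at least 2 nodes, got ", n)
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in node set")
  resno <- as.integer(resno)
  if (length(resno) != n)
    stop("resno length (", length(resno), ") != number of nodes (", n, ")")
  rec <- function(x) {
    x <- as.character(x)
    if (length(x) == 1L) rep(x, n) else x
  }
  chain <- rec(chain); resid <- rec(resid); insert <- rec(insert)
  for (f in c("chain", "resid", "insert"))
    if (length(get(f)) != n)
      stop(f, " length != number of nodes")
  dimnames(xyz) <- list(NULL, c("x", "y", "z"))
  structure(
    list(xyz = xyz, node = seq_len(n) - 1L, resno = resno,
         insert = insert, chain = chain, resid = resid, n = n),
    class = "node_set")
}

#' Validate a node set
#'
#' Checks the structural invariants of a [node_set()]: consistent field
#' lengths, contiguous 0-based node indices, finite coordinates.
#'
#' @param nodes object to validate.
#' @return `nodes`, invisibly, if valid; otherwise an error.
#' @export
validate_node_set <- function(nodes) {
  if (!inherits(nodes, "node_set")) stop("not a node_set")
  n <- nodes$n
  if (n < 2L) stop("node set has fewer than 2 nodes")
  if (nrow(nodes$xyz) != n) stop("xyz row count != n")
  if (!identical(nodes$node, seq_len(n) - 1L))
    stop("node indices are not contiguous 0..N-1")
  if (!all(is.finite(nodes$xyz))) stop("non-finite coordinates")
  for (f in c("resno", "insert", "chain", "resid"))
    if (length(nodes[[f]]) != n) stop("field ", f, " length != n")
  invisible(nodes)
}

#' @export
print.node_set <- function(x, ...) {
  cat("node_set:", x$n, "C-alpha nodes,",
      length(unique(x$chain)), "chain(s)\n")
  cat("  resno range:", min(x$resno), "-", max(x$resno), "\n")
  gaps <- attr(x, "gaps")
  if (!is.null(gaps) && nrow(gaps) > 0L)
    cat("  residue-number gaps:", nrow(gaps), "\n")
  invisible(x)
}

#' @export
as.data.frame.node_set <- function(x, ...) {
  data.frame(node_index = x$node, chain = x$chain, resSeq = x$resno,
             iCode = x$insert, resName = x$resid,
             x = x$xyz[, 1], y = x$xyz[, 2], z = x$xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Write a node table as TSV
#'
#' Emits the tabular dump of a node set: `node_index`, `chain`, `resSeq`,
#' `iCode`, `resName`, `x`, `y`, `z`. The dump is lossless: reading it back
#' with [read_node_table()] reconstructs an identical node set.
#'
#' @param nodes a [node_set()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(nodes, path) {
  validate_node_set(nodes)
  df <- as.data.frame(nodes)
  # full double precision so the round trip is exact
  for (cc in c("x", "y", "z")) df[[cc]] <- sprintf("%.17g", df[[cc]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a node table written by [write_node_table()]
#'
#' @param path TSV file path.
#' @return a [node_set()].
#' @export
read_node_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c(iCode = "character",
                                         chain = "character",
                                         resName = "character"),
                          stringsAsFactors = FALSE)
  df$iCode[is.na(df$iCode)] <- ""
  node_set(cbind(df$x, df$y, df$z), resno = df$resSeq, chain = df$chain,
           resid = df$resName, insert = df$iCode)
}
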