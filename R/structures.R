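#' Re-index a node set over residue-number gaps
#'
#' Crystal structures often lack disordered segments (for vinculin, the
#' flexible linker between the fourth head domain and the tail is absent
#' from the deposited coordinates), leaving jumps in the author residue
#' numbering. The network analyses only use the contiguous node index, so
#' this operation guarantees indices `0..N-1`, preserves the original
#' residue numbers for reporting, and records a gap table listing each jump:
#' the flanking residue numbers and the number of missing residues.
#'
#' Idempotent: re-applying it leaves the node set unchanged.
#'
#' @param nodes a [node_set()].
#' @return the node set with a `gaps` attribute: a data frame with columns
#'   `before` (residue number preceding the gap), `after` (residue number
#'   following it) and `missing` (count of absent residue numbers).
#' @export
reindex_contiguous <- function(nodes) {
  validate_node_set(nodes)
  r <- nodes$resno
  same_chain <- nodes$chain[-1] == nodes$chain[-nodes$n]
  d <- diff(r)
  at <- which(d > 1L & same_chain)
  gaps <- data.frame(before = r[at], after = r[at + 1L],
                     missing = d[at] - 1L)
  nodes$node <- seq_len(nodes$n) - 1L
  attr(nodes, "gaps") <- gaps
  nodes
}

#' Map residue-number ranges onto node-index domain segments
#'
#' Domain definitions come as author residue-number ranges (for example the
#' five-domain partition of vinculin: D1, D2, D3, D4, Vt). This maps them
#' onto contiguous node-index segments of the analysed node set. Residues
#' not covered by any range get the label `"unassigned"`; ranges referring
#' to residue numbers absent from the set are clipped to the residues
#' present, with a warning.
#'
#' @param nodes a [node_set()].
#' @param ranges a list of `list(label, start, end)` (or 3-element vectors)
#'   in author residue numbers, inclusive ends; labels must be unique.
#' @return a `domain_annotation`: data frame with columns `label`,
#'   `start` and `end` (0-based node indices, inclusive), sorted by start,
#'   non-overlapping.
#' @export
assign_domains <- function(nodes, ranges = list()) {
  validate_node_set(nodes)
  n <- nodes$n
  lab <- rep(NA_character_, n)
  if (length(ranges) > 0L) {
    labels <- vapply(ranges, function(r) as.character(r[[1]]), "")
    if (anyDuplicated(labels))
      stop("domain labels must be unique")
    covered <- integer(0)
    for (r in ranges) {
      sel <- which(nodes$resno >= as.integer(r[[2]]) &
                     nodes$resno <= as.integer(r[[3]]))
      if (length(sel) == 0L) {
        warning("range '", r[[1]], "' matches no residues; skipped")
        next
      }
      if (length(sel) < (as.integer(r[[3]]) - as.integer(r[[2]]) + 1L))
        warning("range '", r[[1]],
                "' clipped to residues present in the node set")
      ov <- intersect(sel, covered)
      if (length(ov) > 0L)
        stop("overlapping domain ranges at node indices ",
             paste(utils::head(ov - 1L, 5), collapse = ", "))
      covered <- c(covered, sel)
      lab[sel] <- as.character(r[[1]])
    }
  }
  lab[is.na(lab)] <- "unassigned"
  # compress runs of equal labels into segments
  runs <- rle(lab)
  end <- cumsum(runs$lengths)
  start <- end - runs$lengths + 1L
  ann <- data.frame(label = runs$values, start = start - 1L, end = end - 1L,
                    stringsAsFactors = FALSE)
  class(ann) <- c("domain_annotation", "data.frame")
  ann
}

#' Validate a domain annotation against a node count
#' @param ann a `domain_annotation`.
#' @param n number of nodes the annotation must fit within.
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann, n) {
  if (!inherits(ann, "domain_annotation")) stop("not a domain_annotation")
  if (nrow(ann) == 0L) stop("empty annotation")
  if (any(ann$start > ann$end)) stop("segment with start > end")
  if (any(ann$start < 0L) || any(ann$end > n - 1L))
    stop("segment boundary outside 0..N-1")
  if (is.unsorted(ann$start, strictly = TRUE)) stop("segments not sorted")
  if (any(ann$start[-1] <= ann$end[-nrow(ann)]))
    stop("overlapping segments")
  invisible(ann)
}
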