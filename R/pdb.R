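#' Parse a PDB-format structure into a C-alpha node set
#'
#' Reads fixed-column ATOM records and extracts one node per residue that has
#' a C-alpha atom in the requested chain and model. HETATM records and
#' non-CA atoms are ignored. Where a residue has alternate locations, the
#' highest-occupancy CA is kept (ties broken toward the first-listed record).
#' Residues are distinguished by their (resSeq, iCode) pair and kept in file
#' order.
#'
#' @param pdb_text character: either a single string with embedded newlines,
#'   a character vector of lines, or a path to a PDB file.
#' @param chain chain identifier to select (single character).
#' @param model model number for multi-model files; model 1 by default, the
#'   only model present in crystal structures.
#' @return a [node_set()] with original residue numbers preserved.
#' @export
parse_structure <- function(pdb_text, chain = "A", model = 1L) {
  lines <- .pdb_lines(pdb_text)
  model <- as.integer(model)
  if (length(model) != 1L || is.na(model) || model < 1L)
    stop("model must be a positive integer")

  cur_model <- 1L
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    rec <- substr(lines[i], 1L, 6L)
    if (substr(rec, 1L, 5L) == "MODEL") {
      cur_model <- suppressWarnings(as.integer(trimws(substr(lines[i], 7L, 80L))))
      if (is.na(cur_model)) cur_model <- 1L
    } else if (substr(rec, 1L, 4L) == "ATOM" && cur_model == model) {
      keep[i] <- TRUE
    }
  }
  atom_lines <- lines[keep]
  atom_lnos <- which(keep)
  if (length(atom_lines) == 0L)
    stop("empty selection: no ATOM records for model ", model)

  fld <- function(x, a, b) substr(x, a, b)
  name <- trimws(fld(atom_lines, 13, 16))
  alt <- fld(atom_lines, 17, 17)
  ch <- fld(atom_lines, 22, 22)
  sel <- name == "CA" & ch == chain
  atom_lines <- atom_lines[sel]
  atom_lnos <- atom_lnos[sel]
  alt <- alt[sel]
  if (length(atom_lines) == 0L)
    stop("empty selection: no CA atoms in chain '", chain,
         "', model ", model)

  num <- function(a, b, what) {
    raw <- trimws(fld(atom_lines, a, b))
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) | raw == "")
    if (length(bad) > 0L)
      stop("malformed ATOM record at line ", atom_lnos[bad[1]],
           ": cannot read ", what)
    v
  }
  if (any(nchar(atom_lines) < 54L))
    stop("malformed ATOM record at line ",
         atom_lnos[which(nchar(atom_lines) < 54L)[1]],
         ": truncated before coordinate columns")

  resno <- as.integer(num(23, 26, "residue number"))
  icode <- fld(atom_lines, 27, 27)
  icode[icode == " "] <- ""
  x <- num(31, 38, "x coordinate")
  y <- num(39, 46, "y coordinate")
  z <- num(47, 54, "z coordinate")
  occ_raw <- trimws(fld(atom_lines, 55, 60))
  occ <- suppressWarnings(as.numeric(occ_raw))
  occ[is.na(occ)] <- 1.0
  resid <- trimws(fld(atom_lines, 18, 20))

  # altLoc resolution: within each (resSeq, iCode) keep highest occupancy,
  # first-listed on ties
  key <- paste(resno, icode, sep = "\r")
  ord <- order(match(key, unique(key)), -occ,
               seq_along(key))
  first <- !duplicated(key[ord])
  pick <- sort(ord[first])

  node_set(cbind(x, y, z)[pick, , drop = FALSE], resno = resno[pick],
           chain = chain, resid = resid[pick], insert = icode[pick])
}

.pdb_lines <- function(pdb_text) {
  if (length(pdb_text) == 1L && !grepl("\n", pdb_text) &&
      file.exists(pdb_text)) {
    return(readLines(pdb_text, warn = FALSE))
  }
  unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
}

#' Write a C-alpha trace as a minimal PDB file
#'
#' Emits one fixed-column ATOM record per node. Per-node values (for
#' example per-residue deviations from a superposition) can be written into
#' the B-factor column, the standard trick for color-by-value rendering in
#' any molecular viewer.
#'
#' @param nodes a [node_set()].
#' @param path output path.
#' @param bfactor optional numeric per-node vector for the B-factor column.
#' @return `path`, invisibly.
#' @export
write_pdb_ca <- function(nodes, path, bfactor = NULL) {
  validate_node_set(nodes)
  if (is.null(bfactor)) bfactor <- rep(0, nodes$n)
  if (length(bfactor) != nodes$n)
    stop("bfactor length != number of nodes")
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nodes$n), nodes$resid, nodes$chain, nodes$resno,
    ifelse(nodes$insert == "", " ", nodes$insert),
    nodes$xyz[, 1], nodes$xyz[, 2], nodes$xyz[, 3], 1.0,
    pmin(pmax(bfactor, -99.99), 999.99))
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}
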