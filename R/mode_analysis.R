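#' Slowest-mode fluctuation profile with per-domain statistics
#'
#' The slowest non-rigid mode carries the large-amplitude collective motion
#' that separates a structure into dynamic domains. This returns its
#' normalized squared-fluctuation profile together with the mean and
#' maximum per annotated segment, which turns visual readings ("this
#' domain fluctuates, that hinge is quiet") into numbers.
#'
#' @param spec a [gnm_decompose()] spectrum.
#' @param annotation a [assign_domains()] annotation; `NULL` treats the
#'   whole chain as one segment.
#' @param params an [enm_params()].
#' @param mode which non-rigid mode to profile (default 1, the slowest).
#' @return list with `profile` (per-node, unit sum) and `segments`: a data
#'   frame `label`, `start`, `end`, `mean`, `max`.
#' @export
slow_mode_profile <- function(spec, annotation = NULL,
                              params = enm_params(), mode = 1L) {
  prof <- mode_fluctuation(spec, mode, params)$normalized
  n <- length(prof)
  if (is.null(annotation)) {
    annotation <- data.frame(label = "all", start = 0L, end = n - 1L,
                             stringsAsFactors = FALSE)
    class(annotation) <- c("domain_annotation", "data.frame")
  }
  validate_annotation(annotation, n)
  seg <- annotation
  seg$mean <- vapply(seq_len(nrow(seg)), function(i)
    mean(prof[(seg$start[i] + 1L):(seg$end[i] + 1L)]), 0)
  seg$max <- vapply(seq_len(nrow(seg)), function(i)
    max(prof[(seg$start[i] + 1L):(seg$end[i] + 1L)]), 0)
  list(profile = prof, segments = as.data.frame(seg))
}

# moving average with a shrinking window at the edges
.smooth_profile <- function(x, window) {
  h <- (window - 1L) %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1L, i - h):min(n, i + h)]), 0)
}

#' Detect hinge nodes as prominent minima of a fluctuation profile
#'
#' Hinges between dynamic domains sit at low points of the slow-mode
#' profile. The profile is smoothed with a centred moving average
#' (shrinking window at the edges), then interior local minima are kept if
#' their topographic prominence — the smaller of the rises to the nearest
#' higher ground on either side before a lower point — is at least
#' `prominence` times the profile maximum. The relative threshold makes
#' detection invariant under uniform scaling of the profile. Plateau ties
#' are broken toward the lower node index.
#'
#' @param profile per-node numeric vector (any non-negative scale).
#' @param window odd moving-average width in nodes.
#' @param prominence minimum prominence as a fraction of the profile
#'   maximum, in `[0, 1)`.
#' @return a list of class `hinge_report`: `hinges` (0-based node indices,
#'   ascending), `profile_used` (the smoothed profile), `window`,
#'   `prominence`.
#' @export
find_hinges <- function(profile, window = 5L, prominence = 0.05) {
  n <- length(profile)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("window must be odd and >= 1")
  if (window > n) stop("window (", window, ") larger than profile (", n, ")")
  if (prominence < 0 || prominence >= 1) stop("prominence must be in [0, 1)")
  s <- .smooth_profile(profile, window)
  thr <- prominence * max(s)
  hinges <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    # candidate local minimum: strictly below the previous distinct value,
    # plateau allowed to the right, then strictly rising
    if (s[i] < s[i - 1L]) {
      j <- i
      while (j < n && s[j + 1L] == s[i]) j <- j + 1L
      if (j < n && s[j + 1L] > s[i]) {
        # prominence: climb left and right to nearest higher ground
        left <- max(s[1:(i - 1L)])
        right <- max(s[(j + 1L):n])
        lower_left <- which(s[1:(i - 1L)] < s[i])
        if (length(lower_left) > 0L)
          left <- max(s[(max(lower_left) + 1L):(i - 1L)])
        lower_right <- which(s[(j + 1L):n] < s[i])
        if (length(lower_right) > 0L)
          right <- max(s[(j + 1L):(j + min(lower_right) - 1L)])
        if (min(left, right) - s[i] >= thr)
          hinges <- c(hinges, i - 1L)   # 0-based, lower index of plateau
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  structure(list(hinges = hinges, profile_used = s, window = window,
                 prominence = prominence),
            class = "hinge_report")
}

#' Mean cross-correlation between domain blocks
#'
#' Averages a cross-correlation map over pairs of annotated segments:
#' entry (a, b) is the mean correlation between nodes of segment a and
#' nodes of segment b, with self-pairs excluded on the diagonal blocks.
#' This restates the block structure of a correlation map (which domains
#' move together, which anti-phase) as a small matrix.
#'
#' @param map a [cross_correlation()] result.
#' @param annotation a [assign_domains()] annotation covering the map.
#' @return symmetric segment-by-segment numeric matrix with segment labels
#'   as dimnames.
#' @export
block_correlation <- function(map, annotation) {
  cmat <- map$matrix
  n <- nrow(cmat)
  validate_annotation(annotation, n)
  k <- nrow(annotation)
  idx <- lapply(seq_len(k), function(i)
    (annotation$start[i] + 1L):(annotation$end[i] + 1L))
  if (any(lengths(idx) == 0L)) stop("empty segment in annotation")
  out <- matrix(NA_real_, k, k,
                dimnames = list(annotation$label, annotation$label))
  for (a in seq_len(k)) for (b in seq_len(a)) {
    block <- cmat[idx[[a]], idx[[b]], drop = FALSE]
    if (a == b) {
      if (length(idx[[a]]) < 2L)
        stop("diagonal block for segment '", annotation$label[a],
             "' has no off-diagonal pairs")
      v <- block[lower.tri(block) | upper.tri(block)]
    } else {
      v <- block
    }
    out[a, b] <- out[b, a] <- mean(v)
  }
  out
}
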