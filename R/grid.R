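#' Construct the MAIA 10-2 stimulus grid
#'
#' Builds the 68-locus square-array test grid covering the central macula:
#' the lattice of points with horizontal and vertical offsets of 1, 3, 5, 7
#' or 9 degrees from the meridians, restricted to an eccentricity cut that
#' keeps the standard 10-2 membership. Each locus owns a nonoverlapping
#' 2 degree x 2 degree square centred on it, and loci are connected by a
#' configurable adjacency scheme.
#'
#' Coordinates are field coordinates in degrees: origin at fixation,
#' x positive rightward, y positive upward. No left/right-eye mirroring is
#' applied here; mirroring, if needed, belongs at file I/O.
#'
#' @param eccentricity_cut Radial cut in degrees. Any value in the open
#'   interval (9.06, 9.49) yields the standard 68-locus 10-2 pattern;
#'   values outside that interval are rejected.
#' @param adjacency_scheme One of `"chebyshev8"` (orthogonal and diagonal
#'   neighbours within a Chebyshev distance of 2 degrees, the default),
#'   `"orthogonal4"` (Euclidean distance exactly 2 degrees), or `"custom"`
#'   (supply `custom_edges`).
#' @param custom_edges For `adjacency_scheme = "custom"`: a two-column
#'   data frame or matrix of locus-id pairs. The table is symmetrised and
#'   validated (ids must exist; no self loops).
#'
#' @return An object of class `test_grid`: a list with
#'   \describe{
#'     \item{loci}{data frame with columns `id`, `x`, `y`, `eccentricity`,
#'       one row per locus, sorted by (y descending, x ascending), ids
#'       assigned row-major from the superior-left.}
#'     \item{squares}{data frame `id`, `xmin`, `xmax`, `ymin`, `ymax` —
#'       the tessellation square `[x-1, x+1] x [y-1, y+1]` of each locus.}
#'     \item{adjacency}{named list mapping locus id (as character) to an
#'       integer vector of neighbouring locus ids.}
#'     \item{adjacency_scheme}{the scheme name.}
#'     \item{eccentricity_cut}{the cut used.}
#'   }
#' @examples
#' g <- build_grid()
#' nrow(g$loci)          # 68
#' range(g$loci$x)       # -9 to 9: the grid spans 18 degrees
#' @export
build_grid <- function(eccentricity_cut = 9.2,
                       adjacency_scheme = c("chebyshev8", "orthogonal4", "custom"),
                       custom_edges = NULL) {
  adjacency_scheme <- match.arg(adjacency_scheme)
  if (!is.numeric(eccentricity_cut) || length(eccentricity_cut) != 1L ||
      !is.finite(eccentricity_cut) ||
      eccentricity_cut <= 9.06 || eccentricity_cut >= 9.49) {
    stop("`eccentricity_cut` must lie in the open interval (9.06, 9.49) degrees; ",
         "any such value reproduces the standard 68-locus 10-2 membership.",
         call. = FALSE)
  }
  offs <- c(-9, -7, -5, -3, -1, 1, 3, 5, 7, 9)
  pts <- expand.grid(x = offs, y = offs)
  pts$eccentricity <- sqrt(pts$x^2 + pts$y^2)
  pts <- pts[pts$eccentricity <= eccentricity_cut, , drop = FALSE]
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  loci <- data.frame(id = seq_len(nrow(pts)),
                     x = pts$x, y = pts$y,
                     eccentricity = pts$eccentricity,
                     row.names = NULL)
  squares <- data.frame(id = loci$id,
                        xmin = loci$x - 1, xmax = loci$x + 1,
                        ymin = loci$y - 1, ymax = loci$y + 1)
  grid <- structure(list(loci = loci, squares = squares,
                         adjacency = NULL,
                         adjacency_scheme = adjacency_scheme,
                         eccentricity_cut = eccentricity_cut),
                    class = "test_grid")
  grid$adjacency <- adjacency(grid, adjacency_scheme, custom_edges)
  grid
}

#' Locus adjacency under a named scheme
#'
#' @param grid A `test_grid`.
#' @param scheme `"orthogonal4"` connects loci at Euclidean distance exactly
#'   2 degrees; `"chebyshev8"` connects loci within a Chebyshev distance of
#'   2 degrees (orthogonal plus diagonal); `"custom"` uses `custom_edges`.
#' @param custom_edges Two-column table of locus-id pairs for the custom
#'   scheme; symmetrised automatically.
#' @return Named list: locus id (character) -> sorted integer vector of
#'   neighbour ids. Always symmetric and irreflexive.
#' @export
adjacency <- function(grid, scheme = c("chebyshev8", "orthogonal4", "custom"),
                      custom_edges = NULL) {
  scheme <- match.arg(scheme)
  loci <- grid$loci
  n <- nrow(loci)
  if (scheme == "custom") {
    if (is.null(custom_edges)) {
      stop("`custom_edges` must be supplied for the custom adjacency scheme.",
           call. = FALSE)
    }
    e <- as.matrix(custom_edges)
    if (ncol(e) != 2L) stop("custom adjacency table must have two columns.", call. = FALSE)
    storage.mode(e) <- "integer"
    unknown <- setdiff(unique(as.vector(e)), loci$id)
    if (length(unknown)) {
      stop("custom adjacency references unknown locus ids: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(e[, 1] == e[, 2])) {
      stop("custom adjacency must be irreflexive (no self loops).", call. = FALSE)
    }
    e <- rbind(e, e[, 2:1, drop = FALSE])
    adj <- lapply(loci$id, function(i) sort(unique(e[e[, 1] == i, 2])))
  } else {
    dx <- abs(outer(loci$x, loci$x, "-"))
    dy <- abs(outer(loci$y, loci$y, "-"))
    keep <- if (scheme == "orthogonal4") {
      (dx^2 + dy^2) == 4            # Euclidean distance exactly 2 deg
    } else {
      pmax(dx, dy) <= 2 & (dx + dy) > 0  # Chebyshev <= 2 deg, not self
    }
    diag(keep) <- FALSE
    adj <- lapply(seq_len(n), function(i) loci$id[keep[i, ]])
  }
  names(adj) <- as.character(loci$id)
  adj
}

#' Validate that an adjacency scheme keeps neighbour counts in a range
#'
#' Helper for transcribing externally specified adjacency tables (for
#' example, schemes where each locus has between 2 and 5 neighbours).
#'
#' @param adj Adjacency list as returned by [adjacency()].
#' @param min_neighbors,max_neighbors Inclusive bounds on per-locus degree.
#' @return Invisibly `TRUE`; stops with the offending locus ids otherwise.
#' @export
validate_adjacency_counts <- function(adj, min_neighbors = 2L, max_neighbors = 5L) {
  deg <- vapply(adj, length, integer(1))
  bad <- names(adj)[deg < min_neighbors | deg > max_neighbors]
  if (length(bad)) {
    stop("adjacency degree outside [", min_neighbors, ", ", max_neighbors,
         "] for loci: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' MAIA decibel scale
#'
#' The MAIA expresses stimulus luminance as attenuation in dB relative to
#' its maximum: 0 dB is the brightest stimulus (317.04 cd/m2) and 36 dB the
#' dimmest (0.08 cd/m2). A locus where the brightest stimulus was not seen
#' is exported as -1 dB, a code, not a luminance.
#'
#' @param max_luminance Luminance at 0 dB attenuation, cd/m2.
#' @param range_db Attenuation range, dB.
#' @param floor_code Export code for "not seen at maximum" (outside the
#'   attenuation range).
#' @return A list of class `db_scale`.
#' @export
db_scale <- function(max_luminance = 317.04, range_db = 36, floor_code = -1) {
  stopifnot(max_luminance > 0, range_db > 0,
            floor_code < 0 || floor_code > range_db)
  structure(list(max_luminance = max_luminance, range_db = range_db,
                 floor_code = floor_code),
            class = "db_scale")
}

#' Convert dB attenuation to stimulus luminance
#'
#' @param d Attenuation in dB, within `[0, range_db]`. The floor code is
#'   rejected: "not seen" has no luminance.
#' @param scale A [db_scale()].
#' @return Luminance in cd/m2: `max_luminance * 10^(-d/10)`.
#' @export
db_to_luminance <- function(d, scale = db_scale()) {
  if (any(d == scale$floor_code)) {
    stop("the floor code (", scale$floor_code,
         " dB, 'not seen at maximum') has no luminance.", call. = FALSE)
  }
  if (any(d < 0 | d > scale$range_db)) {
    stop("dB attenuation must lie in [0, ", scale$range_db, "].", call. = FALSE)
  }
  scale$max_luminance * 10^(-d / 10)
}

#' Convert stimulus luminance to dB attenuation
#'
#' Inverse of [db_to_luminance()].
#' @param lum Luminance in cd/m2, positive.
#' @param scale A [db_scale()].
#' @return Attenuation in dB.
#' @export
luminance_to_db <- function(lum, scale = db_scale()) {
  stopifnot(all(lum > 0))
  -10 * log10(lum / scale$max_luminance)
}

#' @export
print.test_grid <- function(x, ...) {
  cat("MAIA 10-2 test grid: ", nrow(x$loci), " loci, span ",
      diff(range(x$loci$x)), " deg, adjacency '", x$adjacency_scheme,
      "'\n", sep = "")
  invisible(x)
}
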