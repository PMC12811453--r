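#' Image pixel-scale specification
#'
#' Square fundus images are described by their field of view (degrees) and
#' resolution (pixels); the MAIA confocal image is 36 degrees over 1024
#' pixels, a short-wavelength autofluorescence image 30 degrees over 768
#' pixels.
#'
#' @param field_of_view Width of the square image in degrees.
#' @param resolution Width of the square image in pixels.
#' @return List of class `image_spec` with a `degrees_per_pixel` field.
#' @export
image_spec <- function(field_of_view, resolution) {
  stopifnot(field_of_view > 0, resolution > 0)
  structure(list(field_of_view = field_of_view, resolution = resolution,
                 degrees_per_pixel = field_of_view / resolution),
            class = "image_spec")
}

#' Least-squares similarity transform from landmark pairs
#'
#' Fits the 2-D similarity transform (isotropic scale, rotation,
#' translation; no shear, no reflection) that maps manually selected source
#' landmarks onto their targets with minimum summed squared residual. With
#' points written as complex numbers the model is `y = a x + b` with
#' `a = scale * exp(i * rotation)`, so the fit is an ordinary complex
#' least-squares regression with a closed-form solution.
#'
#' @param src,dst Two-column matrices (or data frames) of corresponding
#'   points, source and target, in pixels. At least two non-coincident
#'   source points are required.
#' @return Object of class `similarity_transform`: list with `scale`,
#'   `rotation` (radians), `translation` (length-2 vector), `rmse` (root
#'   mean squared residual over all 2n coordinates, pixels), and `n`.
#' @examples
#' src <- cbind(c(0, 100, 0, 100), c(0, 0, 100, 100))
#' t <- fit_similarity(src, src)   # identity, rmse 0
#' @export
fit_similarity <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2L, ncol(dst) == 2L, nrow(src) == nrow(dst))
  if (nrow(src) < 2L) {
    stop("at least two landmark pairs are required.", call. = FALSE)
  }
  if (anyDuplicated(src)) {
    stop("duplicate source landmarks.", call. = FALSE)
  }
  x <- complex(real = src[, 1], imaginary = src[, 2])
  y <- complex(real = dst[, 1], imaginary = dst[, 2])
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sum(Mod(xc)^2)
  if (denom == 0) {
    stop("degenerate landmark configuration: all source points coincide.",
         call. = FALSE)
  }
  a <- sum(Conj(xc) * yc) / denom
  b <- mean(y) - a * mean(x)
  resid <- y - (a * x + b)
  structure(list(scale = Mod(a), rotation = Arg(a),
                 translation = c(Re(b), Im(b)),
                 rmse = sqrt(sum(Mod(resid)^2) / (2 * length(x))),
                 n = length(x)),
            class = "similarity_transform")
}

#' Apply a similarity transform to points
#'
#' @param t A `similarity_transform`.
#' @param pts Two-column matrix of points.
#' @param inverse Apply the inverse mapping instead.
#' @return Transformed two-column matrix.
#' @export
apply_similarity <- function(t, pts, inverse = FALSE) {
  pts <- as.matrix(pts)
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  a <- complex(modulus = t$scale, argument = t$rotation)
  b <- complex(real = t$translation[1], imaginary = t$translation[2])
  w <- if (inverse) (z - b) / a else a * z + b
  cbind(Re(w), Im(w))
}

#' Identity similarity transform
#' @return A `similarity_transform` with scale 1, rotation 0, translation 0.
#' @export
identity_transform <- function() {
  structure(list(scale = 1, rotation = 0, translation = c(0, 0),
                 rmse = 0, n = 0L),
            class = "similarity_transform")
}

#' Ring-boundary polygon in grid degrees
#'
#' Validates and normalises a closed boundary polygon: the first vertex is
#' not repeated at the end internally, the polygon must have at least three
#' distinct vertices and be simple (non-self-intersecting). Incomplete
#' rings are rejected from analysis rather than silently used.
#'
#' @param vertices Two-column matrix of vertices in degrees relative to the
#'   grid centre (x right, y up). A duplicated closing vertex is dropped.
#' @param is_complete Whether the traced ring is complete; incomplete rings
#'   cannot be analysed.
#' @return Object of class `ring_polygon` (list with `vertices`,
#'   `is_complete`).
#' @export
ring_polygon <- function(vertices, is_complete = TRUE) {
  v <- as.matrix(vertices)
  stopifnot(ncol(v) == 2L)
  if (nrow(v) >= 2L && all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  if (nrow(v) < 3L) {
    stop("a ring polygon needs at least 3 distinct vertices.", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("non-finite ring vertices.", call. = FALSE)
  if (!is_complete) {
    stop("incomplete ring: rings not fully traceable are excluded from analysis.",
         call. = FALSE)
  }
  if (.self_intersects(v)) {
    stop("ring polygon is self-intersecting.", call. = FALSE)
  }
  structure(list(vertices = v, is_complete = is_complete),
            class = "ring_polygon")
}

# Brute-force simplicity check over non-adjacent edge pairs.
.self_intersects <- function(v) {
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    if (i == 1L) js <- js[js != n]      # edge n is adjacent to edge 1
    if (!length(js)) next
    hit <- .seg_seg_intersect(a[i, ], b[i, ],
                              a[js, , drop = FALSE], b[js, , drop = FALSE])
    if (any(hit)) return(TRUE)
  }
  FALSE
}

# Vectorised proper/improper segment intersection: segment p1-p2 against
# rows of q1/q2. Touching endpoints count as intersection.
.seg_seg_intersect <- function(p1, p2, q1, q2) {
  d1x <- p2[1] - p1[1]; d1y <- p2[2] - p1[2]
  d2x <- q2[, 1] - q1[, 1]; d2y <- q2[, 2] - q1[, 2]
  denom <- d1x * d2y - d1y * d2x
  rx <- q1[, 1] - p1[1]; ry <- q1[, 2] - p1[2]
  tnum <- rx * d2y - ry * d2x
  unum <- rx * d1y - ry * d1x
  out <- logical(nrow(q1))
  gen <- denom != 0
  tt <- tnum[gen] / denom[gen]; uu <- unum[gen] / denom[gen]
  out[gen] <- tt >= 0 & tt <= 1 & uu >= 0 & uu <= 1
  # parallel: overlap only if collinear and projections overlap
  par <- !gen & (tnum == 0)
  if (any(par)) {
    L2 <- d1x^2 + d1y^2
    s1 <- ((q1[par, 1] - p1[1]) * d1x + (q1[par, 2] - p1[2]) * d1y) / L2
    s2 <- ((q2[par, 1] - p1[1]) * d1x + (q2[par, 2] - p1[2]) * d1y) / L2
    out[par] <- pmax(pmin(s1, s2), 0) <= pmin(pmax(s1, s2), 1)
  }
  out
}

#' Map a pixel-space ring boundary into grid degrees
#'
#' Vertices traced in autofluorescence-image pixels are carried into MAIA
#' pixels through a landmark-fitted similarity transform, then converted to
#' degrees relative to the grid centre using the MAIA pixel scale. Image
#' rows increase downward while field y increases upward, so y is negated.
#'
#' @param ring_px Two-column matrix of ring vertices in source-image pixels
#'   (or a `ring_polygon` whose vertices are in pixels).
#' @param t `similarity_transform` from source pixels to MAIA pixels; use
#'   [identity_transform()] when the ring is already in MAIA pixels.
#' @param maia [image_spec()] of the MAIA image (36 deg / 1024 px).
#' @param grid_center_px Pixel coordinates of the grid centre in the MAIA
#'   image; defaults to the image centre.
#' @return A `ring_polygon` in degrees.
#' @export
ring_to_degrees <- function(ring_px, t = identity_transform(),
                            maia = image_spec(36, 1024),
                            grid_center_px = c(maia$resolution / 2,
                                               maia$resolution / 2)) {
  v <- if (inherits(ring_px, "ring_polygon")) ring_px$vertices else as.matrix(ring_px)
  maia_px <- apply_similarity(t, v)
  deg <- sweep(maia_px, 2, grid_center_px) * maia$degrees_per_pixel
  deg[, 2] <- -deg[, 2]
  ring_polygon(deg)
}

#' Polygonize a circle or ellipse at bounded chord length
#'
#' Discretises an analytic ring at a chord length small enough (default
#' 0.25 degrees) that transection tests are accurate to well under 0.05
#' degrees.
#'
#' @param center Centre, degrees.
#' @param radius Semi-axis along x, degrees.
#' @param axis_ratio Ratio of the y semi-axis to `radius` (1 = circle).
#' @param rotation Rotation of the ellipse axes, radians.
#' @param max_chord Maximum chord length, degrees.
#' @return A `ring_polygon`.
#' @export
polygonize_ring <- function(center = c(0, 0), radius, axis_ratio = 1,
                            rotation = 0, max_chord = 0.25) {
  stopifnot(radius > 0, axis_ratio > 0, max_chord > 0)
  rmax <- radius * max(1, axis_ratio)
  n <- max(16L, ceiling(2 * pi / (2 * asin(min(1, max_chord / (2 * rmax))))))
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  px <- radius * cos(th); py <- radius * axis_ratio * sin(th)
  x <- center[1] + px * cos(rotation) - py * sin(rotation)
  y <- center[2] + px * sin(rotation) + py * cos(rotation)
  ring_polygon(cbind(x, y))
}

#' Does a ring boundary transect a tessellation square?
#'
#' `TRUE` iff at least one boundary edge of the polygon meets the closed
#' axis-aligned square (touching the square's boundary counts). A square
#' strictly inside or strictly outside the ring, with no boundary contact,
#' is not transected.
#'
#' @param square Numeric vector `c(xmin, xmax, ymin, ymax)` in degrees, or
#'   a one-row slice of `test_grid$squares`.
#' @param ring A `ring_polygon` in degrees.
#' @return Logical flag.
#' @export
transects <- function(square, ring) {
  sq <- .square_vec(square)
  v <- ring$vertices
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1), , drop = FALSE]
  any(.seg_in_rect(a, b, sq[1], sq[2], sq[3], sq[4]))
}

.square_vec <- function(square) {
  if (is.data.frame(square)) {
    as.numeric(square[1, c("xmin", "xmax", "ymin", "ymax")])
  } else {
    as.numeric(square)
  }
}

# Vectorised Liang-Barsky: does segment a->b intersect the closed rectangle?
.seg_in_rect <- function(a, b, xmin, xmax, ymin, ymax) {
  dx <- b[, 1] - a[, 1]; dy <- b[, 2] - a[, 2]
  t0 <- rep(0, nrow(a)); t1 <- rep(1, nrow(a))
  ok <- rep(TRUE, nrow(a))
  clip <- function(p, q, t0, t1, ok) {
    nz <- p != 0
    r <- ifelse(nz, q / p, Inf)
    ent <- nz & p < 0
    ext <- nz & p > 0
    t0 <- ifelse(ent, pmax(t0, r), t0)
    t1 <- ifelse(ext, pmin(t1, r), t1)
    ok <- ok & !(!nz & q < 0)      # parallel and outside this slab
    list(t0 = t0, t1 = t1, ok = ok)
  }
  s <- clip(-dx, a[, 1] - xmin, t0, t1, ok)
  s <- clip(dx, xmax - a[, 1], s$t0, s$t1, s$ok)
  s <- clip(-dy, a[, 2] - ymin, s$t0, s$t1, s$ok)
  s <- clip(dy, ymax - a[, 2], s$t0, s$t1, s$ok)
  s$ok & s$t0 <= s$t1
}

#' Transection flags for every square of a grid
#'
#' @param grid A `test_grid`.
#' @param ring A `ring_polygon` in degrees.
#' @return Logical vector, one flag per locus, in `grid$loci` order.
#' @export
transects_grid <- function(grid, ring) {
  v <- ring$vertices
  n <- nrow(v)
  a <- v; b <- v[c(2:n, 1), , drop = FALSE]
  sq <- grid$squares
  vapply(seq_len(nrow(sq)),
         function(i) any(.seg_in_rect(a, b, sq$xmin[i], sq$xmax[i],
                                      sq$ymin[i], sq$ymax[i])),
         logical(1))
}

#' Is a point inside a ring polygon?
#'
#' Even-odd ray-casting test; points on the boundary are treated as inside.
#' @param pts Two-column matrix of points.
#' @param ring A `ring_polygon`.
#' @return Logical vector.
#' @export
point_in_ring <- function(pts, ring) {
  pts <- as.matrix(pts)
  v <- ring$vertices
  n <- nrow(v)
  xs <- v[, 1]; ys <- v[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_len(nrow(pts)), function(k) {
    px <- pts[k, 1]; py <- pts[k, 2]
    crosses <- ((ys > py) != (ye > py)) &
      (px < (xe - xs) * (py - ys) / (ye - ys) + xs)
    sum(crosses) %% 2L == 1L
  }, logical(1))
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf("similarity transform: scale %.6g, rotation %.6g rad, translation (%.6g, %.6g), rmse %.3g px (n = %d)\n",
              x$scale, x$rotation, x$translation[1], x$translation[2],
              x$rmse, x$n))
  invisible(x)
}

#' @export
print.ring_polygon <- function(x, ...) {
  cat("ring polygon: ", nrow(x$vertices), " vertices, complete\n", sep = "")
  invisible(x)
}
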