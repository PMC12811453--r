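# Independent brute-force oracles used to cross-check the package's
# geometry and selection code. These deliberately use different algorithms
# from the implementation (orientation tests instead of Liang-Barsky
# clipping; plain loops instead of vectorised set logic).

# cross product orientation of (b - a) x (c - a)
.orient <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

.on_segment <- function(a, b, p) {
  min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
    min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
}

# classic orientation-based segment intersection (touching counts)
oracle_seg_intersect <- function(p1, p2, p3, p4) {
  d1 <- .orient(p3, p4, p1); d2 <- .orient(p3, p4, p2)
  d3 <- .orient(p1, p2, p3); d4 <- .orient(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  (d1 == 0 && .on_segment(p3, p4, p1)) ||
    (d2 == 0 && .on_segment(p3, p4, p2)) ||
    (d3 == 0 && .on_segment(p1, p2, p3)) ||
    (d4 == 0 && .on_segment(p1, p2, p4))
}

# does any polygon edge meet the closed rectangle? brute force: endpoint
# containment or intersection with one of the 4 sides
oracle_transects <- function(square, verts) {
  xmin <- square[1]; xmax <- square[2]; ymin <- square[3]; ymax <- square[4]
  n <- nrow(verts)
  inside <- verts[, 1] >= xmin & verts[, 1] <= xmax &
    verts[, 2] >= ymin & verts[, 2] <= ymax
  if (any(inside)) return(TRUE)
  corners <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  sides <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (i in seq_len(n)) {
    a <- verts[i, ]; b <- verts[if (i == n) 1L else i + 1L, ]
    for (s in sides) {
      if (oracle_seg_intersect(a, b, corners[[s[1]]], corners[[s[2]]])) {
        return(TRUE)
      }
    }
  }
  FALSE
}

# vectorised variant of oracle_transects over all polygon edges, still
# built on orientation tests (independent of the Liang-Barsky clipping the
# package uses); for bulk randomized cross-checks
oracle_transects_fast <- function(square, verts) {
  xmin <- square[1]; xmax <- square[2]; ymin <- square[3]; ymax <- square[4]
  if (any(verts[, 1] >= xmin & verts[, 1] <= xmax &
            verts[, 2] >= ymin & verts[, 2] <= ymax)) return(TRUE)
  n <- nrow(verts)
  a <- verts; b <- verts[c(2:n, 1), , drop = FALSE]
  corners <- rbind(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax), c(xmin, ymax))
  sides <- cbind(1:4, c(2, 3, 4, 1))
  cross2 <- function(ox, oy, px, py, qx, qy) {
    (px - ox) * (qy - oy) - (py - oy) * (qx - ox)
  }
  for (s in 1:4) {
    c1 <- corners[sides[s, 1], ]; c2 <- corners[sides[s, 2], ]
    d1 <- cross2(c1[1], c1[2], c2[1], c2[2], a[, 1], a[, 2])
    d2 <- cross2(c1[1], c1[2], c2[1], c2[2], b[, 1], b[, 2])
    d3 <- cross2(a[, 1], a[, 2], b[, 1], b[, 2], c1[1], c1[2])
    d4 <- cross2(a[, 1], a[, 2], b[, 1], b[, 2], c2[1], c2[2])
    proper <- ((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))
    if (any(proper)) return(TRUE)
    # collinear touching: an endpoint exactly on the side (rare for random
    # rings, but kept for completeness)
    on1 <- d1 == 0 & a[, 1] >= min(c1[1], c2[1]) & a[, 1] <= max(c1[1], c2[1]) &
      a[, 2] >= min(c1[2], c2[2]) & a[, 2] <= max(c1[2], c2[2])
    on2 <- d2 == 0 & b[, 1] >= min(c1[1], c2[1]) & b[, 1] <= max(c1[1], c2[1]) &
      b[, 2] >= min(c1[2], c2[2]) & b[, 2] <= max(c1[2], c2[2])
    if (any(on1 | on2)) return(TRUE)
  }
  FALSE
}

# exact analytic transection test for a circle: the boundary meets the
# closed square iff dmin <= radius <= dmax (nearest point / farthest corner)
oracle_circle_transects <- function(square, center, radius) {
  xmin <- square[1]; xmax <- square[2]; ymin <- square[3]; ymax <- square[4]
  dx <- pmax(pmax(xmin - center[1], 0), center[1] - xmax)
  dy <- pmax(pmax(ymin - center[2], 0), center[2] - ymax)
  dmin <- sqrt(dx^2 + dy^2)
  cx <- c(xmin, xmax); cy <- c(ymin, ymax)
  dmax <- sqrt(max(outer((cx - center[1])^2, (cy - center[2])^2, "+")))
  dmin <= radius && radius <= dmax
}

# how close the circle is to merely grazing the square: distance from the
# radius to the nearest of the square's min/max distances from the centre
oracle_circle_gap <- function(square, center, radius) {
  xmin <- square[1]; xmax <- square[2]; ymin <- square[3]; ymax <- square[4]
  dx <- max(xmin - center[1], 0, center[1] - xmax)
  dy <- max(ymin - center[2], 0, center[2] - ymax)
  dmin <- sqrt(dx^2 + dy^2)
  cx <- c(xmin, xmax); cy <- c(ymin, ymax)
  dmax <- sqrt(max(outer((cx - center[1])^2, (cy - center[2])^2, "+")))
  min(abs(radius - dmin), abs(radius - dmax))
}

# plain-loop edge-of-scotoma selection
oracle_ess <- function(values, grid) {
  out <- integer(0)
  for (i in grid$loci$id) {
    if (values[i] == -1) next
    nb <- grid$adjacency[[as.character(i)]]
    if (any(values[nb] == -1)) out <- c(out, i)
  }
  out
}

# plain-loop mFTP selection: proportions, then whole tiers until >= 5
oracle_mftp <- function(values, grid, min_loci = 5) {
  props <- c()
  ids <- c()
  for (i in grid$loci$id) {
    if (values[i] < 8) next
    nb <- grid$adjacency[[as.character(i)]]
    if (!length(nb)) next
    p <- sum(values[nb] <= values[i] - 7) / length(nb)
    props <- c(props, p); ids <- c(ids, i)
  }
  keep <- props > 0
  props <- props[keep]; ids <- ids[keep]
  if (!length(ids)) return(integer(0))
  sel <- ids[props == 1]
  tiers <- sort(unique(props[props < 1]), decreasing = TRUE)
  for (tv in tiers) {
    if (length(sel) >= min_loci) break
    sel <- c(sel, ids[props == tv])
  }
  sort(sel)
}

# from-scratch sums-of-squares partition for the within-subjects one-way
# ANOVA (rows = subjects, columns = conditions)
oracle_rm_anova_F <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ss_subj <- k * sum((rowMeans(m) - grand)^2)
  ss_cond <- n * sum((colMeans(m) - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_cond
  (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
}

# random sensitivity fields: a noisy radial hill with a random floor
# radius, integer-valued and floor-censored like a real export
random_field <- function(grid, scotoma_prob = 0.5) {
  r0 <- runif(1, 2, 9)
  mu <- -5 + 29 * plogis((r0 - grid$loci$eccentricity) / runif(1, 0.5, 2.5))
  v <- round(mu + rnorm(nrow(grid$loci), 0, 2))
  if (runif(1) > scotoma_prob) v <- pmax(v, sample(0:10, 1))  # no/low scotoma variant
  v[v < 0] <- -1
  v[v > 36] <- 36
  as.integer(v)
}

grid68 <- build_grid()
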