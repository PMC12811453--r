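test_that("similarity fit recovers a known transform exactly", {
  set.seed(42)
  src <- matrix(runif(16, 0, 768), ncol = 2)
  a <- complex(modulus = 1.3, argument = 0.2)
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- a * z + complex(real = 10, imaginary = -5)
  t <- fit_similarity(src, cbind(Re(w), Im(w)))
  expect_equal(t$scale, 1.3, tolerance = 1e-9)
  expect_equal(t$rotation, 0.2, tolerance = 1e-9)
  expect_equal(t$translation, c(10, -5), tolerance = 1e-9)
  expect_lt(t$rmse, 1e-9)
  # identity pairs
  ti <- fit_similarity(src, src)
  expect_equal(ti$scale, 1, tolerance = 1e-12)
  expect_equal(ti$rotation, 0, tolerance = 1e-12)
  expect_equal(ti$rmse, 0, tolerance = 1e-12)
  # degenerate configurations
  expect_error(fit_similarity(src[1, , drop = FALSE], src[1, , drop = FALSE]),
               "two landmark")
  same <- matrix(5, 3, 2)
  expect_error(fit_similarity(same + 0, same), "duplicate|coincide")
})

test_that("landmark rmse matches its least-squares expectation under noise", {
  set.seed(7)
  n <- 6
  src <- matrix(runif(2 * n, 0, 700), ncol = 2)
  sigma <- 2
  rmses <- replicate(400, {
    dst <- src * 1.1 + matrix(rnorm(2 * n, 0, sigma), ncol = 2)
    fit_similarity(src, dst)$rmse
  })
  # E[RSS] = sigma^2 (2n - 4) with 4 fitted parameters over 2n coordinates
  expected <- sigma * sqrt((2 * n - 4) / (2 * n))
  expect_equal(sqrt(mean(rmses^2)), expected, tolerance = 0.05)
})

test_that("similarity fit is rotation-equivariant", {
  set.seed(3)
  src <- matrix(runif(10, 0, 100), ncol = 2)
  dst <- matrix(runif(10, 0, 100), ncol = 2)
  t0 <- fit_similarity(src, dst)
  theta <- 0.31
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  t1 <- fit_similarity(src %*% t(R), dst)
  expect_equal(t1$rotation, t0$rotation - theta, tolerance = 1e-9)
  expect_equal(t1$scale, t0$scale, tolerance = 1e-9)
})

test_that("ring mapping applies the printed pixel scales and flips y", {
  maia <- image_spec(36, 1024)
  ctr <- c(512, 512)
  # circle of radius 100 MAIA px around the grid centre -> 3.515625 deg
  th <- seq(0, 2 * pi, length.out = 129)[-129]
  ring_px <- cbind(512 + 100 * cos(th), 512 + 100 * sin(th))
  ring <- ring_to_degrees(ring_px, identity_transform(), maia, ctr)
  r <- sqrt(rowSums(ring$vertices^2))
  expect_equal(r, rep(100 * 36 / 1024, length(r)), tolerance = 1e-9)
  # a vertex above the centre in image rows (smaller y) maps to positive
  # field y
  up_px <- rbind(c(512, 412), c(612, 512), c(512, 612))
  up <- ring_to_degrees(up_px, identity_transform(), maia, ctr)
  expect_gt(up$vertices[1, 2], 0)
  expect_equal(up$vertices[2, ], c(100 * 36 / 1024, 0), tolerance = 1e-9)
})

test_that("degrees are invariant to which image the ring was measured in", {
  af <- image_spec(30, 768); maia <- image_spec(36, 1024)
  ctr_m <- c(512, 512); ctr_a <- c(384, 384)
  # the same physical 3-degree circle measured in AF pixels, mapped through
  # the pure-scale AF->MAIA transform, must land on the 3-degree circle
  th <- seq(0, 2 * pi, length.out = 97)[-97]
  deg <- cbind(3 * cos(th), 3 * sin(th))
  ring_af <- sweep(cbind(deg[, 1], -deg[, 2]) / af$degrees_per_pixel, 2, ctr_a, "+")
  s <- af$degrees_per_pixel / maia$degrees_per_pixel
  t_af_maia <- structure(list(scale = s, rotation = 0,
                              translation = ctr_m - s * ctr_a,
                              rmse = 0, n = 0L),
                         class = "similarity_transform")
  ring <- ring_to_degrees(ring_af, t_af_maia, maia, ctr_m)
  expect_equal(sqrt(rowSums(ring$vertices^2)), rep(3, 96), tolerance = 1e-9)
})

test_that("ring polygons are validated: closure, simplicity, completeness", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  r <- ring_polygon(rbind(sq, sq[1, ]))        # closing vertex normalised away
  expect_equal(nrow(r$vertices), 4)
  expect_error(ring_polygon(sq[1:2, ]), "3 distinct")
  bowtie <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))
  expect_error(ring_polygon(bowtie), "self-intersecting")
  expect_error(ring_polygon(sq, is_complete = FALSE), "incomplete")
})

test_that("square transection matches geometry on hand cases", {
  ring <- polygonize_ring(radius = 3.52)
  # square of locus (3,1): nearest corner at sqrt(4), farthest sqrt(16+4);
  # 3.52 lies between, so the circle crosses it
  expect_true(transects(c(2, 4, 0, 2), ring))
  # square of locus (9,1): nearest corner at sqrt(64) = 8 > 3.52
  expect_false(transects(c(8, 10, 0, 2), ring))
  # ring containing the whole grid: no square touched
  big <- polygonize_ring(radius = 30)
  expect_false(any(transects_grid(grid68, big)))
  # ring strictly inside one square: only that square
  tiny <- polygonize_ring(center = c(1, 1), radius = 0.4)
  hits <- transects_grid(grid68, tiny)
  expect_equal(sum(hits), 1)
  expect_equal(grid68$loci[hits, c("x", "y")],
               data.frame(x = 1, y = 1), ignore_attr = TRUE)
})

test_that("transection agrees with independent oracles on random rings", {
  set.seed(11)
  sq <- grid68$squares
  for (rep in 1:60) {
    ctr <- runif(2, -6, 6)
    if (rep %% 2) {
      r <- runif(1, 0.5, 9)
      ring <- polygonize_ring(center = ctr, radius = r, max_chord = 0.05)
      oracle <- vapply(seq_len(nrow(sq)), function(i) {
        oracle_circle_transects(as.numeric(sq[i, c("xmin", "xmax", "ymin", "ymax")]),
                                ctr, r)
      }, logical(1))
    } else {
      ring <- polygonize_ring(center = ctr, radius = runif(1, 0.5, 7),
                              axis_ratio = runif(1, 0.5, 1.5),
                              rotation = runif(1, 0, pi))
      oracle <- vapply(seq_len(nrow(sq)), function(i) {
        oracle_transects(as.numeric(sq[i, c("xmin", "xmax", "ymin", "ymax")]),
                         ring$vertices)
      }, logical(1))
    }
    got <- transects_grid(grid68, ring)
    if (rep %% 2) {
      # discretized polygon vs analytic circle: disagreement is tolerated
      # only where the true circle grazes the square within the bounded
      # polygonization error
      mism <- which(got != oracle)
      for (i in mism) {
        s <- as.numeric(sq[i, c("xmin", "xmax", "ymin", "ymax")])
        expect_lt(oracle_circle_gap(s, ctr, r), 0.01)
      }
    } else {
      expect_equal(got, oracle, info = paste("rep", rep))
    }
  }
})

test_that("transected squares are invariant under 90-degree rotations", {
  set.seed(5)
  g <- grid68
  for (rep in 1:20) {
    ring <- polygonize_ring(center = runif(2, -3, 3), radius = runif(1, 1, 7),
                            axis_ratio = runif(1, 0.6, 1.4))
    base <- transects_grid(g, ring)
    v <- ring$vertices
    rot <- ring_polygon(cbind(-v[, 2], v[, 1]))   # +90 degrees
    rotated <- transects_grid(g, rot)
    # match squares through the same rotation of locus coordinates
    key <- paste(g$loci$x, g$loci$y)
    rkey <- paste(-g$loci$y, g$loci$x)
    expect_equal(rotated[match(rkey, key)], base)
  }
})
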