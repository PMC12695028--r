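test_that("EMD matches brute-force enumeration and its closed-form example", {
  # parallel segments at unit separation, equal x sampling, no alignment
  x <- seq(0, 1, length.out = 50L)
  a <- as_outline(cbind(x, 0))
  b <- as_outline(cbind(x, 1))
  expect_equal(dist_emd(a, b), 2)
  expect_equal(dist_emd(a, a), 0)

  battery <- tooth_battery(6L, 64L)
  for (i in 1:5) {
    u <- battery[[i]]; v <- battery[[i + 1L]]
    expect_equal(dist_emd(u, v), emd_brute(u, v), tolerance = 1e-12)
    expect_identical(dist_emd(u, v), dist_emd(v, u))
  }
})

test_that("HED equals twice the mean positionwise distance and the general form", {
  o <- make_tooth(tooth_params(2, 0, cusp_height = 0.5), 80L)
  b <- shift_outline(o, 0, 0.37)
  expect_equal(dist_hed(o, b), 2 * 0.37, tolerance = 1e-12)
  expect_equal(dist_hed(o, o), 0)
  # equal counts: the general relative-position formula coincides
  p <- make_tooth(tooth_params(3, 0, cusp_height = 0.4), 80L)
  expect_equal(dist_hed(o, p), hed_brute(o, p), tolerance = 1e-12)
  # unequal counts fall back to the general matching
  q <- resample_outline(p, 50L)
  expect_equal(dist_hed(o, q), hed_brute(o, q), tolerance = 1e-12)
})

test_that("SAO overlap matches pixel-count enumeration and its bounds", {
  a <- resample_outline(rect_outline(2, 1), 81L)
  expect_equal(sao_overlap(a, a), 1)
  b <- shift_outline(a, 5, 0)      # disjoint
  expect_equal(sao_overlap(a, b), 0)
  # equal rectangles overlapping exactly half their area
  c2 <- shift_outline(a, 1, 0)
  g <- sao_grid(unclass(a), unclass(c2), 100L)
  got <- sao_overlap(a, c2, grid = g)
  expect_equal(got, 0.5, tolerance = 0.02)   # one pixel-quantization unit
  # brute-force pixel classification oracle on a coarse grid
  g2 <- sao_grid(unclass(a), unclass(c2), 25L)
  expect_equal(sao_overlap(a, c2, grid = g2), sao_brute(a, c2, g2),
               tolerance = 1e-12)
  t1 <- tooth_battery(2L, 48L)
  g3 <- sao_grid(unclass(t1[[1]]), unclass(t1[[2]]), 20L)
  expect_equal(sao_overlap(t1[[1]], t1[[2]], grid = g3),
               sao_brute(t1[[1]], t1[[2]], g3), tolerance = 1e-12)
})

test_that("cosine transform round-trips and orders reconstruction error", {
  o <- center_and_scale(make_tooth(tooth_params(5, 0, cusp_height = 0.4), 128L),
                        "length")
  cf <- dct_outline(o, harmonics = 127L)
  rec <- inverse_dct(cf, 128L)
  expect_lt(max(abs(unclass(rec) - unclass(o))), 1e-6)
  err <- function(k) {
    r <- inverse_dct(dct_outline(o, k), 128L)
    sqrt(mean((unclass(r) - unclass(o))^2))
  }
  expect_lt(err(24L), err(6L))
  # constant coordinate stream has no non-DC energy
  seg <- as_outline(cbind(seq(0, 1, length.out = 32L), 0))
  cf2 <- dct_outline(seg, 10L)
  expect_lt(max(abs(cf2$coef[, 2L])), 1e-12)
})

test_that("DFD is a metric on cosine coefficients", {
  tri <- tooth_battery(3L, 64L)
  tri <- lapply(tri, center_and_scale, mode = "length")
  d12 <- dist_dfd(tri[[1]], tri[[2]])
  d13 <- dist_dfd(tri[[1]], tri[[3]])
  d23 <- dist_dfd(tri[[2]], tri[[3]])
  expect_equal(dist_dfd(tri[[1]], tri[[1]]), 0)
  expect_identical(d12, dist_dfd(tri[[2]], tri[[1]]))
  expect_lte(d13, d12 + d23 + 1e-12)
  expect_gte(d12, 0)
})

test_that("the angle function is linear on straight lines and exact on arcs", {
  seg <- as_outline(cbind(seq(0, 1, length.out = 100L), 0))
  af <- angle_function(seg, 100L)
  expect_equal(as.numeric(attr(af, "angles")), rep(pi, 98L), tolerance = 1e-9)
  expect_equal(as.numeric(af), pi * seq_len(98L), tolerance = 1e-9)

  # quarter-circle arc: every interior angle is pi - (arc turn per step)
  phi <- pi / 2
  t <- seq(0, phi, length.out = 100L)
  arc <- as_outline(cbind(cos(t), sin(t)))
  afa <- angle_function(arc, 100L)
  expect_equal(as.numeric(attr(afa, "angles")), rep(pi - phi / 99, 98L),
               tolerance = 1e-6)

  # similarity invariance
  o <- make_tooth(tooth_params(2, 0, cusp_height = 0.5), 120L)
  o2 <- shift_outline(as_outline(unclass(o) * 3), 2, -1)
  expect_equal(unclass(angle_function(o, 100L)),
               unclass(angle_function(o2, 100L)), tolerance = 1e-9)
})

test_that("OAD accumulates the area between anchored angle functions", {
  seg <- as_outline(cbind(seq(0, 2, length.out = 100L), 0))
  bend <- resample_outline(as_outline(cbind(c(0, 1, 1), c(0, 0, 1))), 100L)
  expect_equal(dist_oad(seg, seg), 0)
  expect_identical(dist_oad(seg, bend), dist_oad(bend, seg))
  # brute force: enumerate both cumulative angle step functions directly
  af_brute <- function(o) {
    p <- unclass(resample_outline(o, 100L))
    ang <- numeric(98L)
    for (i in 2:99) {
      u <- p[i - 1L, ] - p[i, ]; v <- p[i + 1L, ] - p[i, ]
      ang[i - 1L] <- acos(max(-1, min(1, sum(u * v) /
                                        sqrt(sum(u^2) * sum(v^2)))))
    }
    cumsum(ang)
  }
  # acos is boundary-sensitive for near-straight triplets; compare at the
  # accuracy the angle evaluation itself supports
  expect_equal(dist_oad(seg, bend),
               sum(abs(af_brute(seg) - af_brute(bend))), tolerance = 1e-6)
})

test_that("ADD is Parseval-consistent with the anchored angle functions", {
  a <- make_tooth(tooth_params(1, 0, cusp_height = 0.6), 120L)
  b <- make_tooth(tooth_params(3, 0, cusp_height = 0.4), 120L)
  expect_equal(dist_add(a, a), 0)
  expect_identical(dist_add(a, b), dist_add(b, a))
  # at full rank, the coefficient distance equals the L2 norm of the
  # mean-centered difference of the angle functions (orthonormal basis)
  fa <- unclass(angle_function(a, 100L))
  fb <- unclass(angle_function(b, 100L))
  d <- fa - fb
  full <- dist_add(a, b, harmonics = 97L)
  expect_equal(full, sqrt(sum((d - mean(d))^2)), tolerance = 1e-9)
})

test_that("mean shapes average cosine coefficients", {
  o <- center_and_scale(make_tooth(tooth_params(2, 0, cusp_height = 0.5), 100L),
                        "length")
  m2 <- mean_shape(list(o, o))
  expect_lt(max(abs(unclass(m2) - unclass(o))), 1e-9)
  m5 <- mean_shape(rep(list(o), 5L))
  expect_equal(unclass(m5), unclass(m2), tolerance = 1e-12)
  # mean of a shape and its mirror image is mirror-symmetric
  p <- unclass(o)
  mir <- as_outline(cbind(-p[rev(seq_len(nrow(p))), 1L],
                          p[rev(seq_len(nrow(p))), 2L]))
  ms <- unclass(mean_shape(list(o, mir)))
  msm <- cbind(-ms[rev(seq_len(nrow(ms))), 1L], ms[rev(seq_len(nrow(ms))), 2L])
  expect_lt(max(abs(ms - msm)), 1e-9)
  expect_error(mean_shape(list()), "empty")
})

test_that("the distance tensor agrees with single-pair calls and is symmetric", {
  teeth <- list(make_tooth(tooth_params(1, 0, cusp_height = 0.5), 64L),
                make_tooth(tooth_params(2, 0, cusp_height = 0.5), 64L),
                make_tooth(tooth_params(3, 0, cusp_height = 0.4), 64L))
  dent <- dentition("fix", upper = teeth)
  spec <- align_grid_spec(5L, 3L, 3L)
  tn <- pairwise_distances(dent, search = spec, n_points = 64L)
  for (m in names(tn$d)) {
    expect_true(isSymmetric(tn$d[[m]]))
    expect_true(all(diag(tn$d[[m]]) == 0))
    expect_true(all(tn$d[[m]] >= 0))
  }
  prep <- lapply(teeth, function(o)
    center_and_scale(resample_outline(o, 64L), "length"))
  expect_equal(tn$d$EMD[1, 2],
               align_pair(prep[[1]], prep[[2]], "EMD", spec)$distance,
               tolerance = 1e-12)
  expect_equal(tn$d$DFD[1, 3], dist_dfd(prep[[1]], prep[[3]]),
               tolerance = 1e-12)
  expect_equal(tn$d$OAD[2, 3], dist_oad(prep[[2]], prep[[3]]),
               tolerance = 1e-12)
  # SAO stored as a distance: identical teeth score 0
  dent2 <- dentition("homo", upper = list(teeth[[1]], teeth[[1]]))
  tn2 <- pairwise_distances(dent2, search = spec, n_points = 64L)
  expect_equal(max(vapply(tn2$d, max, 0)), 0)
})
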