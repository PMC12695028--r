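test_that("cusp counting separates major cusps from sub-threshold cusplets", {
  smooth <- center_and_scale(make_tooth(tooth_params(1, 0, cusp_height = 0.5),
                                        500L), "length")
  expect_identical(count_cusps(smooth), c(major = 1L, minor = 0L))

  # a gently sloped crown carrying 6 sub-threshold cusplets
  serrated <- center_and_scale(
    make_tooth(tooth_params(1, 6, cusp_height = 0.25,
                            minor_cusp_height = 0.008), 1000L), "length")
  cc <- count_cusps(serrated)
  expect_identical(unname(cc["major"]), 1L)
  expect_identical(unname(cc["minor"]), 6L)

  flat <- as_outline(cbind(seq(0, 1, length.out = 50L), 0))
  expect_identical(count_cusps(flat), c(major = 0L, minor = 0L))

  # the largest extremum is always major, even when sub-threshold
  tiny <- center_and_scale(make_tooth(tooth_params(1, 0, cusp_height = 0.02,
                                                   smoothness = 0.05), 500L),
                           "length")
  expect_gte(unname(count_cusps(tiny)["major"]), 1L)
})

test_that("OAR matches the half-disc closed form and scales as 1/size", {
  semi <- semicircle(2001L)
  expect_equal(oar(semi), 2, tolerance = 1e-3)   # pi*r / (pi*r^2/2), r = 1
  semi3 <- as_outline(unclass(semi) * 3)
  expect_equal(oar(semi3), 2 / 3, tolerance = 1e-3)
})

test_that("OCR matches the circle closed form and is resolution-dependent", {
  n <- 1000L
  t <- seq(0, 2 * pi * (1 - 1 / n), length.out = n)
  circ <- as_outline(cbind(cos(t), sin(t)))
  expect_equal(ocr(circ), 2 * pi / sqrt(n), tolerance = 1e-2)
  n2 <- 2000L
  t2 <- seq(0, 2 * pi * (1 - 1 / n2), length.out = n2)
  circ2 <- as_outline(cbind(cos(t2), sin(t2)))
  expect_equal(ocr(circ2) / ocr(circ), 1 / sqrt(2), tolerance = 1e-2)
})

test_that("OIR matches closed forms, the brute-force grid oracle, and its cap", {
  # disc: inscribed and escribed circles coincide
  t <- seq(0, 2 * pi * 0.9995, length.out = 721L)
  disc <- as_outline(cbind(cos(t), sin(t)))
  expect_equal(oir(disc), 1, tolerance = 0.02)
  # 2x1 rectangle: r = 0.5, R = sqrt(5)/2, area ratio 5
  rect <- resample_outline(rect_outline(2, 1), 401L)
  expect_equal(oir(rect), 5, tolerance = 0.02)
  # brute-force inradius oracle on a small polygon
  small <- resample_outline(rect_outline(2, 1), 41L)
  r_pkg <- heterodont:::cpp_inradius(unclass(small), 256L, 3L)
  r_brute <- inradius_brute(small, 100L)
  expect_equal(r_pkg, r_brute, tolerance = 0.02)
  # needle-like sliver engages the cap
  sliver <- resample_outline(rect_outline(50, 0.5), 401L)
  expect_equal(oir(sliver), 25)
})

test_that("shape undulation moves cosine coefficient mass to higher harmonics", {
  one <- center_and_scale(make_tooth(tooth_params(1, 0, cusp_height = 0.5),
                                     500L), "length")
  five <- center_and_scale(make_tooth(tooth_params(5, 0, cusp_height = 0.5),
                                      500L), "length")
  high_frac <- function(o) {
    cf <- abs(dct_outline(o, 24L)$coef)
    sum(cf[5:24, ]) / sum(cf)
  }
  expect_gt(high_frac(five), high_frac(one))
  expect_gte(dfs(five), 0)
  expect_identical(dfs(one), dfs(one))  # deterministic
})

test_that("angle measures vanish on straight lines and match arc closed forms", {
  seg <- as_outline(cbind(seq(0, 1, length.out = 1000L), 0))
  ladder <- resolution_ladder(1000L)
  am <- angle_complexity(seg, ladder)
  expect_equal(am$ANS, 0, tolerance = 1e-6)
  expect_equal(am$ASC, 0, tolerance = 1e-6)
  expect_equal(am$AND, 0, tolerance = 1e-6)

  # semicircular arc at resolution n: each deviation is pi/(n-1)
  semi <- semicircle(2001L)
  am2 <- angle_complexity(semi, ladder)
  expected_A <- vapply(ladder, function(nr) pi * (nr - 2) / (nr - 1), 0.0)
  expect_equal(am2$A, expected_A, tolerance = 1e-3)
  expect_equal(am2$AND, 0, tolerance = 1e-3)  # equiangular at every resolution
})

test_that("resolution ladder follows the halving rule", {
  expect_identical(resolution_ladder(1000L), c(200L, 100L, 50L, 25L, 13L, 6L))
  expect_warning(lad <- resolution_ladder(100L), "fewer than 3")
  expect_true(all(lad >= 3L))
  expect_true(all(diff(resolution_ladder(1000L)) < 0))
})

test_that("OPC counts direction streaks and refines monotonically", {
  seg <- as_outline(cbind(seq(0, 1, length.out = 200L), 0))
  expect_equal(opc(seg, ladder = c(50L, 25L)), 1)

  # square-wave zigzag alternating between two sectors: streaks = number of
  # direction alternations + 1, verified by enumeration for one config
  n <- 40L
  zig <- as_outline(cbind(seq_len(n), rep(c(0, 1), length.out = n)))
  count <- opc_brute_one(zig, 4L, 0)
  v <- diff(unclass(zig))
  alternations <- sum(diff(atan2(v[, 2], v[, 1])) != 0)
  expect_identical(count, as.integer(alternations + 1L))

  # refining partitions never decreases the streak count (fixed resolution)
  for (o in tooth_battery(3L, 100L)) {
    p <- resample_outline(o, 50L)
    c2 <- opc_brute_one(p, 2L, 0)
    c4 <- opc_brute_one(p, 4L, 0)
    c8 <- opc_brute_one(p, 8L, 0)
    expect_lte(c2, c4)
    expect_lte(c4, c8)
  }
})

test_that("species aggregation averages teeth and normalizes globally", {
  tooth <- make_tooth(tooth_params(2, 0, cusp_height = 0.5), 200L)
  homo <- dentition("homo", upper = list(tooth, tooth), lower = list(tooth))
  single <- suppressWarnings(tooth_complexity(tooth, n_points = 200L))
  other <- make_tooth(tooth_params(1, 4, cusp_height = 0.7,
                                   minor_cusp_height = 0.05), 200L)
  hetero <- dentition("hetero", upper = list(other, other), lower = list(other))
  tab <- suppressWarnings(species_complexity(list(homo, hetero), n_points = 200L))
  for (m in heterodont:::complexity_measure_names()) {
    expect_equal(tab[[m]][tab$species == "homo"], single[[m]],
                 tolerance = 1e-9)
    expect_true(all(tab[[paste0(m, ".norm")]] %in% c(0, 1)))
  }
  expect_true(all(tab$Cx_combined >= 0 & tab$Cx_combined <= 10))
  expect_error(species_complexity(list()), "no dentitions")
})

test_that("cusp ratio uses the zero-major convention", {
  t1 <- make_tooth(tooth_params(2, 4, cusp_height = 0.6,
                                minor_cusp_height = 0.008), 300L)
  t2 <- make_tooth(tooth_params(1, 0, cusp_height = 0.5), 300L)
  tab <- suppressWarnings(
    species_complexity(list(dentition("a", upper = list(t1)),
                            dentition("b", upper = list(t2))),
                       n_points = 300L))
  expect_equal(tab$cusp_ratio[tab$species == "a"],
               tab$CUSP2[tab$species == "a"] / tab$CUSP1[tab$species == "a"])
  expect_equal(tab$cusp_ratio[tab$species == "b"], 0)
})
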