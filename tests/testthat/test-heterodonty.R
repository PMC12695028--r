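dmat <- function(v) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

test_that("jaw statistics match their printed closed forms on tiny rows", {
  d2 <- dmat(0.4)                       # 2 teeth, distance delta
  expect_equal(hms(d2), 0.4 / 2)        # (d + d) / (2 * 2)
  expect_equal(hmt(d2), 2 * 0.4 / 4)    # 2 delta / n^2
  expect_equal(hmx(d2), 0.4)

  # 3-tooth row with distinct distances: naive double-loop oracle
  d3 <- dmat(c(0.1, 0.3, 0.2))  # d12 = .1, d13 = .3, d23 = .2
  hms_naive <- (0.1 + (0.1 + 0.2) + 0.2) / (2 * 3)
  hmt_naive <- sum(d3) / 9
  expect_equal(hms(d3), hms_naive)
  expect_equal(hmt(d3), hmt_naive)
  expect_equal(hmx(d3), 0.3)
  expect_equal(hmx(d3), max(d3))        # brute-force max over the slice
  # the "mean" boundary variant divides by the number of existing terms
  expect_equal(hms(d3, boundary = "mean"), (0.1 + 0.1 + 0.2 + 0.2) / 4)
})

test_that("HMS is reversal-invariant and HMT permutation-invariant", {
  set.seed(5)
  v <- runif(10)
  d5 <- dmat(v)
  rev_idx <- 5:1
  expect_equal(hms(d5[rev_idx, rev_idx]), hms(d5))
  for (i in 1:5) {
    p <- sample(5)
    expect_equal(hmt(d5[p, p]), hmt(d5))
    expect_equal(hmx(d5[p, p]), hmx(d5))
  }
})

test_that("homodont rows score zero under every statistic", {
  z <- matrix(0, 4, 4)
  expect_equal(hms(z), 0)
  expect_equal(hmt(z), 0)
  expect_equal(hmx(z), 0)
  expect_error(hms(matrix(0, 1, 1)), "at least 2")
})

test_that("HMX is never below HMT", {
  set.seed(8)
  for (i in 1:20) {
    d <- dmat(runif(15))
    expect_gte(hmx(d), hmt(d))
  }
})

test_that("dignathic heterodonty matches the directed matching rules", {
  # identical jaws: zero
  expect_equal(hdg(matrix(0, 3, 3)), 0)
  # equal counts, uniform cross distance delta: each directed mean = delta
  u <- matrix(0.25, 4, 4)
  expect_equal(hdg(u), 0.5)
  # unequal counts: matching indices equal the brute-force minimizer
  expect_identical(heterodont:::match_relative(3L, 6L),
                   match_relative_brute(3L, 6L))
  expect_identical(heterodont:::match_relative(6L, 3L),
                   match_relative_brute(6L, 3L))
  expect_identical(heterodont:::match_relative(7L, 5L),
                   match_relative_brute(7L, 5L))
  set.seed(2)
  dc <- matrix(runif(18), 3, 6)
  k <- match_relative_brute(3L, 6L)
  l <- match_relative_brute(6L, 3L)
  manual <- mean(dc[cbind(1:3, k)]) + mean(dc[cbind(l, 1:6)])
  expect_equal(hdg(dc), manual)
})

test_that("phenotypic distance is zero on self and symmetric on uniform offsets", {
  z <- matrix(0, 4, 4)
  expect_equal(phenotypic_distance(z, z), 0)
  u <- matrix(0.3, 4, 4)
  expect_equal(phenotypic_distance(u, u), 0.6)  # 2 delta, averaged over jaws
  set.seed(3)
  a <- matrix(runif(16), 4, 4)
  expect_equal(phenotypic_distance(a, t(a)), phenotypic_distance(t(a), a))
})

test_that("species records and aggregation normalize to the dataset extremes", {
  base <- tooth_params(1, 0, cusp_height = 0.5)
  dents <- lapply(1:3, function(i) {
    g <- c(0, 0.25, 0.5)[i]
    make_dentition(dentition_params(
      n_teeth_upper = 3, n_teeth_lower = 3, base = base,
      monognathic_gradient = list(elongation = g, asymmetry = 0.5 * g),
      dignathic_offset = list(elongation = 0.2 + 0.3 * g),
      seed = 10 + i), species = paste0("sp", i), n_points = 80L)
  })
  tn <- pairwise_distances(tooth_table(dents),
                           search = align_grid_spec(5L, 3L, 3L),
                           n_points = 80L)
  rec <- heterodonty_records(tn)
  tab <- heterodonty_table(rec)
  for (st in c("HMS", "HMT", "HDG", "HMX")) {
    expect_true(all(tab[[st]] >= 0 & tab[[st]] <= 1))
    for (m in distance_measures()) {
      col <- tab[[paste0(st, "_", m, ".norm")]]
      expect_equal(min(col), 0)
      expect_equal(max(col), 1)
    }
  }
  # per-measure statistics equal direct evaluation of the tensor slices
  d_emd_sp2_up <- heterodont:::tensor_slice(tn, "EMD", "sp2", "upper")
  expect_equal(rec$HMS[rec$species == "sp2" & rec$measure == "EMD"],
               mean(c(hms(d_emd_sp2_up),
                      hms(heterodont:::tensor_slice(tn, "EMD", "sp2", "lower")))))
  expect_error(heterodonty_table(rec[rec$species == "sp1", ]), "at least 2")
})

test_that("offset-only dentitions have zero monognathic but positive dignathic values", {
  dents <- lapply(1:2, function(i) {
    off <- c(0.3, 0.6)[i]
    make_dentition(dentition_params(
      n_teeth_upper = 3, n_teeth_lower = 3,
      dignathic_offset = list(elongation = off), seed = 1),
      species = paste0("off", i), n_points = 80L)
  })
  tn <- pairwise_distances(tooth_table(dents),
                           search = align_grid_spec(5L, 3L, 3L),
                           n_points = 80L)
  rec <- heterodonty_records(tn)
  expect_equal(max(rec$HMS), 0)
  expect_equal(max(rec$HMT), 0)
  expect_true(all(rec$HDG > 0))
  tab <- heterodonty_table(rec)
  expect_true(all(is.na(tab$graduality) | tab$graduality == 0))
})
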