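# A deterministic pair table over k species with a caterpillar-like dG
# structure and two clades for taxonomy tests.
toy_pairs <- function(k = 10L, trait_vals = seq_len(k)) {
  sp <- sprintf("s%02d", seq_len(k))
  tax <- data.frame(species = sp,
                    family = rep(c("famA", "famB"), each = k / 2),
                    order = rep(c("ordA", "ordB"), each = k / 2),
                    superorder = rep(c("supA", "supB"), each = k / 2))
  half <- function(ss) paste(sprintf("%s:%d", ss, seq_along(ss)),
                             collapse = ",")
  tr <- ape::read.tree(text = sprintf("((%s):10,(%s):10);",
                                      half(sp[1:(k / 2)]),
                                      half(sp[(k / 2 + 1):k])))
  measures <- data.frame(species = sp, trait = trait_vals)
  list(measures = measures, dg = dg_table(tr), tax = tax)
}

test_that("the pair table enumerates all unordered pairs, sorted by dG", {
  x <- toy_pairs(10L)
  tab <- build_pair_table(x$measures, x$dg, x$tax)
  expect_identical(nrow(tab), 45L)
  expect_true(!is.unsorted(tab$dG))
  expect_true(all(tab$species_a != tab$species_b))
  # identical trait values across species give zero differences
  same <- build_pair_table(data.frame(species = x$measures$species, trait = 5),
                           x$dg)
  expect_true(all(same$diff_trait == 0))
  # deterministic order across repeated builds (ties broken by name)
  expect_identical(build_pair_table(x$measures, x$dg, x$tax), tab)
  bad <- x$measures
  bad$species[1] <- "zz"
  expect_error(build_pair_table(bad, x$dg), "species sets differ")
})

test_that("the sliding rank test separates an increasing trait and stays flat on noise", {
  n_sp <- 40L
  sp <- sprintf("s%02d", 1:n_sp)
  dg <- data.frame(species_a = rep(sp, each = n_sp)[rep(upper.tri(diag(n_sp)), 1)],
                   species_b = rep(sp, n_sp)[rep(upper.tri(diag(n_sp)), 1)])
  prs <- t(combn(sp, 2))
  dg <- data.frame(species_a = prs[, 1], species_b = prs[, 2])
  dg$dG <- seq(0, 1, length.out = nrow(dg))
  inc <- make_trait_table(dg, "increasing", noise_sd = 0, seed = 4)
  names(inc)[names(inc) == "trait_diff"] <- "diff_t"
  res <- sliding_scan(inc, "diff_t", window = 100L, offset = 200L)
  expect_true(all(res$p < 0.05))
  expect_identical(nrow(res), nrow(inc) - 2L * 100L - 200L + 1L)
  expect_true(all(res$p > 0 & res$p <= 1))
  # the anchor is the dG of the top of the lower window
  expect_equal(res$dG_anchor[1], inc$dG[100])
  expect_error(sliding_scan(inc[1:100, ], "diff_t", 100L, 0L), "at least")
})

test_that("offset-separated windows yield stronger significance on ordered traits", {
  prs <- t(combn(sprintf("s%02d", 1:40), 2))
  dg <- data.frame(species_a = prs[, 1], species_b = prs[, 2],
                   dG = seq(0, 1, length.out = nrow(prs)))
  tab <- make_trait_table(dg, "increasing", noise_sd = 0.4, seed = 9)
  names(tab)[names(tab) == "trait_diff"] <- "diff_t"
  p0 <- sliding_scan(tab, "diff_t", 100L, 0L)
  p200 <- sliding_scan(tab, "diff_t", 100L, 200L)
  expect_lte(median(p200$p), median(p0$p))
})

test_that("p-values are calibrated on an independent trait", {
  prs <- t(combn(sprintf("s%02d", 1:40), 2))
  dg <- data.frame(species_a = prs[, 1], species_b = prs[, 2],
                   dG = seq(0, 1, length.out = nrow(prs)))
  tab <- make_trait_table(dg, "independent", noise_sd = 1, seed = 11)
  names(tab)[names(tab) == "trait_diff"] <- "diff_t"
  res <- sliding_scan(tab, "diff_t", 100L, 0L)
  expect_lt(abs(mean(res$p < 0.05) - 0.05), 0.06)
})

test_that("window composition fractions are exact and sum to one", {
  x <- toy_pairs(10L)
  tab <- build_pair_table(x$measures, x$dg, x$tax)
  comp <- composition_annotation(tab, window = 10L)
  lv <- c("same_family", "same_order", "same_superorder",
          "different_superorders")
  expect_equal(unname(rowSums(comp[lv])), rep(1, nrow(comp)))
  # direct count for the first window
  rel <- tab$relation[1:10]
  for (l in lv) expect_equal(comp[[l]][1], mean(rel == l))
  # two-clade structure: lowest-dG windows are dominated by within-clade pairs
  expect_gt(comp$same_family[1], comp$same_family[nrow(comp)])
  # all species in one family
  tax1 <- x$tax
  tax1$family <- "famA"; tax1$order <- "ordA"; tax1$superorder <- "supA"
  tab1 <- build_pair_table(x$measures, x$dg, tax1)
  comp1 <- composition_annotation(tab1, window = 10L)
  expect_true(all(comp1$same_family == 1))
  expect_error(composition_annotation(x$dg, 5L), "relation")
})
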