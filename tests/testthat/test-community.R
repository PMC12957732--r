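test_that("Bray-Curtis matches hand values and respects its bounds", {
  x <- rbind(s1 = c(1, 0), s2 = c(1, 1))
  expect_equal(as.numeric(bray_curtis(x, mode = "raw")), 1 / 3)

  ident <- rbind(a = c(3, 2, 1), b = c(3, 2, 1))
  expect_equal(as.numeric(bray_curtis(ident, mode = "raw")), 0)
  disjoint <- rbind(a = c(5, 0), b = c(0, 7))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)

  set.seed(1)
  m <- matrix(rpois(60, 4) + 1, nrow = 6)
  d <- as.numeric(bray_curtis(m))
  expect_true(all(d >= 0 & d <= 1))

  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 2))), "all-zero")
})

test_that("relative-mode Bray-Curtis is invariant to per-sample depth", {
  set.seed(2)
  m <- matrix(rpois(50, 10) + 1, nrow = 5,
              dimnames = list(paste0("s", 1:5), NULL))
  m2 <- m
  m2[3, ] <- m2[3, ] * 10
  expect_equal(as.numeric(bray_curtis(m)), as.numeric(bray_curtis(m2)))
  # presence-absence mode only sees support
  m3 <- m
  m3[m3 > 0] <- m3[m3 > 0] + 5
  expect_equal(as.numeric(bray_curtis(m, "presence_absence")),
               as.numeric(bray_curtis(m3, "presence_absence")))
})

test_that("PCoA reproduces Euclidean configurations exactly", {
  set.seed(3)
  pts <- cbind(runif(7, 0, 10), runif(7, 0, 10))
  d <- dist(pts)
  ord <- pcoa_ord(d, k = 2)
  expect_equal(as.numeric(dist(ord$points)), as.numeric(d),
               tolerance = 1e-9)
  expect_false(ord$reduced)
  # points on a line embed in one axis
  dl <- dist(matrix(c(0, 3, 7), ncol = 1))
  ordl <- pcoa_ord(dl, k = 1)
  expect_equal(as.numeric(dist(ordl$points)), as.numeric(dl),
               tolerance = 1e-9)
})

test_that("NMDS reaches near-zero stress on embeddable input and is seeded", {
  set.seed(4)
  pts <- cbind(runif(12, 0, 5), runif(12, 0, 5))
  d <- dist(pts)
  o1 <- suppressWarnings(nmds_ord(d, k = 2, n_starts = 5, seed = 7))
  expect_lt(o1$stress, 0.01)
  o2 <- suppressWarnings(nmds_ord(d, k = 2, n_starts = 5, seed = 7))
  expect_identical(o1$points, o2$points)
  expect_true(o1$stress >= 0 && o1$stress <= 1)
})

test_that("PERMANOVA agrees with brute-force enumeration on a tiny instance", {
  set.seed(5)
  m <- matrix(rpois(6 * 4, 6) + 1, nrow = 6)
  m[1:3, 1] <- m[1:3, 1] + 4     # mild group signal
  d <- bray_curtis(m, mode = "raw")
  grp <- rep(c("a", "b"), each = 3)

  # oracle: every distinct assignment of 3 samples to group a
  combos <- combn(6, 3)
  f_all <- apply(combos, 2, function(idx) {
    g <- rep("b", 6); g[idx] <- "a"
    oracle_permanova_f(d, g)
  })
  f_obs <- oracle_permanova_f(d, grp)
  p_exact <- mean(f_all >= f_obs - 1e-12)

  res <- permanova(d, grp, n_perm = 4999, seed = 11)
  expect_equal(res$f, f_obs, tolerance = 1e-10)
  mc_se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(res$p - p_exact), 3 * mc_se + 2 / 5000)
})

test_that("PERMANOVA matches the reference implementation and its invariants", {
  ds <- simulate_dataset(small_config(seed = 17, fish_per_reef = 5))
  fish <- ds$fish[ds$fish$species == "browser", ]
  otu <- ds$otu[fish$id, ]
  d <- bray_curtis(otu)
  res <- permanova(d, fish$zone, n_perm = 999, seed = 1)
  ref <- vegan::adonis2(as.matrix(otu / rowSums(otu)) ~ zone,
                        data = fish, permutations = 199, method = "bray")
  expect_equal(res$f, ref$F[1], tolerance = 1e-8)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-8)
  expect_gte(res$p, 1 / 1000)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)

  # Monte-Carlo error across seeds stays within the binomial bound
  p1 <- permanova(d, fish$zone, n_perm = 2000, seed = 2)$p
  p2 <- permanova(d, fish$zone, n_perm = 2000, seed = 3)$p
  expect_lt(abs(p1 - p2), 3 * sqrt(0.5 * 0.5 / 2000) + 1e-3)

  expect_error(permanova(d, rep("a", attr(d, "Size"))), "2 groups")
  expect_error(permanova(d, c("a", rep("b", attr(d, "Size") - 1))),
               "at least 2 samples")
})

test_that("widely separated clusters reach the minimal attainable p", {
  # enough samples that a random relabelling essentially never recreates
  # the two-cluster partition (the permutation floor is far below 1/1000)
  set.seed(6)
  m <- rbind(matrix(rpois(12 * 6, 3), nrow = 12),
             matrix(rpois(12 * 6, 3) + 200, nrow = 12))
  d <- bray_curtis(m, mode = "raw")
  res <- permanova(d, rep(c("lo", "hi"), each = 12), n_perm = 999, seed = 4)
  expect_equal(res$p, 1 / 1000)
})

test_that("pairwise PERMANOVA applies Bonferroni and isolates a displaced group", {
  set.seed(9)
  base <- matrix(rpois(12 * 6, 8) + 1, nrow = 12)
  displaced <- matrix(rpois(6 * 6, 8) + 1, nrow = 6)
  displaced[, 1:2] <- displaced[, 1:2] + 120
  m <- rbind(base, displaced)
  grp <- rep(c("g1", "g2", "g3"), c(6, 6, 6))
  d <- bray_curtis(m, mode = "raw")
  pw <- pairwise_permanova(d, grp, n_perm = 999, seed = 2)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$p_adjusted >= pw$p - 1e-12))
  expect_true(all(pw$p_adjusted <= 1))
  sig <- pw$p_adjusted < 0.05
  involves_g3 <- pw$group1 == "g3" | pw$group2 == "g3"
  expect_true(all(sig[involves_g3]))
  expect_false(any(sig[!involves_g3]))
})
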