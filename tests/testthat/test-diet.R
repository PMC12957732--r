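toy_taxonomy <- function() {
  data.frame(otu_id = c("o1", "o2", "o3"),
             phylum = c("Annelida", "Annelida", "Cnidaria"),
             genus = c("Loimia", NA, "Porites"),
             stringsAsFactors = FALSE)
}

test_that("taxonomic aggregation conserves reads and pools unassigned ranks", {
  x <- rbind(f1 = c(o1 = 3L, o2 = 7L, o3 = 2L),
             f2 = c(o1 = 0L, o2 = 1L, o3 = 9L))
  tax <- toy_taxonomy()
  ph <- aggregate_taxa(x, tax, "phylum")
  expect_equal(ph[, "Annelida"], c(f1 = 10, f2 = 1))
  expect_equal(ph[, "Cnidaria"], c(f1 = 2, f2 = 9))
  expect_equal(sum(ph), sum(x))
  gn <- aggregate_taxa(x, tax, "genus")
  expect_true("unassigned" %in% colnames(gn))
  expect_equal(gn[, "unassigned"], c(f1 = 7, f2 = 1))
  expect_equal(sum(gn), sum(x))
  expect_error(aggregate_taxa(x, tax, "kingdom"), "unknown rank")
  expect_error(aggregate_taxa(cbind(x, o9 = c(1L, 1L)), tax, "phylum"),
               "missing from the taxonomy")
})

test_that("relative abundance and presence-absence behave as contracts state", {
  x <- rbind(a = c(2, 2), b = c(9, 1))
  rel <- relative_abundance(x)
  expect_equal(rel["a", ], c(0.5, 0.5))
  expect_equal(unname(rowSums(rel)), c(1, 1))
  # proportions times depth reproduce the counts
  expect_equal(rel * rowSums(x), x)
  expect_error(relative_abundance(rbind(a = c(0, 0), b = c(1, 1))),
               "all-zero")
  pa <- presence_absence(rbind(c(9, 10, 0)), min_reads = 10)
  expect_equal(as.numeric(pa), c(0, 1, 0))
})

test_that("rarefaction matches exhaustive enumeration and rises with samples", {
  x <- rbind(f1 = c(1L, 0L, 0L, 2L),
             f2 = c(0L, 3L, 0L, 1L),
             f3 = c(0L, 0L, 4L, 0L))
  rc <- rarefaction_curve(x, n_draws = 50)
  # oracle: average richness over the three possible pairs
  rich_pair <- function(i, j) sum(colSums(x[c(i, j), ]) > 0)
  expect_equal(rc$mean_richness[rc$s == 2],
               mean(c(rich_pair(1, 2), rich_pair(1, 3), rich_pair(2, 3))))
  expect_true(all(rc$exact))
  # endpoints: per-sample mean and total richness with zero spread
  expect_equal(rc$mean_richness[rc$s == 1],
               mean(rowSums(x > 0)))
  expect_equal(rc$mean_richness[rc$s == 3], sum(colSums(x) > 0))
  expect_equal(rc$sd_richness[rc$s == 3], 0)

  ds <- simulate_dataset(small_config(seed = 23, fish_per_reef = 4))
  fish <- ds$fish[ds$fish$species == "predator", ]
  rcg <- rarefaction_curve(ds$otu[fish$id, ], groups = fish$zone,
                           n_draws = 200, seed = 1)
  for (g in unique(rcg$group))
    expect_true(all(diff(rcg$mean_richness[rcg$group == g]) > -1e-9))
})

test_that("Amundsen points follow the FO and prey-specific abundance formulas", {
  # prey A only in fish 1 at half its reads: FO 25, P_i 50
  x <- rbind(f1 = c(A = 5, B = 5),
             f2 = c(A = 0, B = 10),
             f3 = c(A = 0, B = 7),
             f4 = c(A = 0, B = 3))
  am <- amundsen(x)
  a_row <- am[am$prey == "A", ]
  expect_equal(a_row$fo, 25)
  expect_equal(a_row$pi, 50)
  expect_equal(a_row$quadrant, "BPC-leaning")
  # a prey that is the sole item everywhere sits at (100, 100)
  sole <- amundsen(cbind(only = c(4, 9, 2)))
  expect_equal(sole$fo, 100)
  expect_equal(sole$pi, 100)
  expect_equal(sole$quadrant, "dominant-specialized")
  # with relative abundance, P_i for an omnipresent prey is its mean share
  set.seed(3)
  m <- matrix(rpois(40, 20) + 1, nrow = 5)
  colnames(m) <- paste0("p", 1:8)
  am2 <- amundsen(m)
  rel <- m / rowSums(m)
  expect_equal(am2$pi[am2$prey == "p1"], 100 * mean(rel[, "p1"]))
  # FO and P_i are invariant to per-fish depth rescaling
  m2 <- m
  m2[2, ] <- m2[2, ] * 50
  expect_equal(amundsen(m2)$fo, am2$fo)
  expect_equal(amundsen(m2)$pi, am2$pi)
  expect_error(amundsen(m[0, , drop = FALSE]), "empty")
})

test_that("prey GLMM detects a strong simulated coral-cover effect", {
  set.seed(12)
  n_reef <- 9
  fish_per_reef <- 20
  cover <- rep(c(33, 30, 36, 12, 10, 14, 0.4, 0.3, 0.2), each = fish_per_reef)
  reef <- rep(paste0("r", 1:n_reef), each = fish_per_reef)
  zone <- rep(c("outer", "inner", "dist"), each = 3 * fish_per_reef)
  depth <- rep(10000, n_reef * fish_per_reef)
  slope <- 0.05
  reef_eff <- rnorm(n_reef, 0, 0.2)[rep(1:n_reef, each = fish_per_reef)]
  mu <- exp(log(0.02) + slope * cover + reef_eff + log(depth))
  y <- rnbinom(length(mu), mu = mu, size = 5)
  fit <- fit_prey_glmm(y, cover, zone, reef, depth = depth)
  expect_lt(fit$p, 0.001)
  expect_gte(fit$chisq, 0)
  expect_equal(fit$df, 1L)
  # recovered slope within 2 SE of the generating value
  expect_lt(abs(fit$estimate - slope), 2 * fit$se)
})

test_that("prey GLMM agrees with an independent NB mixed-model fitter", {
  skip_if_not_installed("lme4")
  set.seed(4)
  reef <- rep(paste0("r", 1:9), each = 10)
  zone <- rep(c("a", "b", "c"), each = 30)
  age <- sample(3:9, 90, replace = TRUE)
  y <- rnbinom(90, mu = exp(2 + 0.2 * age), size = 8)
  fit <- fit_prey_glmm(y, age, zone, reef, mode = "mimic",
                       transform = "none")
  ref <- suppressMessages(suppressWarnings(
    lme4::glmer.nb(y ~ age + (1 | zone / reef),
                   data = data.frame(y = y, age = age, zone = zone,
                                     reef = reef))))
  ref_coef <- lme4::fixef(ref)[["age"]]
  expect_equal(fit$estimate, ref_coef, tolerance = 0.02)
})

test_that("mimic mode applies the documented response transformations", {
  set.seed(6)
  reef <- rep(paste0("r", 1:6), each = 8)
  zone <- rep(c("a", "b", "c"), each = 16)
  pred <- runif(48, 0, 30)
  y <- rnbinom(48, mu = 50, size = 3)
  f4 <- fit_prey_glmm(y, pred, zone, reef, mode = "mimic",
                      transform = "fourth_root")
  expect_equal(f4$transform, "fourth_root")
  expect_equal(f4$mode, "mimic")
  expect_error(fit_prey_glmm(y, rep(1, 48), zone, reef, mode = "mimic"),
               "does not vary")
  expect_error(fit_prey_glmm(y, pred, zone, reef, mode = "offset"),
               "requires depth")
})
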