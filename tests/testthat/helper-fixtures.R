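# Shared fixtures for the test suite. Everything is generated in code;
# nothing is read from disk.

# small, fast configuration (fewer fish than the study design)
small_config <- function(seed = 1, fish_per_reef = 6, ...) {
  sim_config(seed = seed, fish_per_reef = fish_per_reef, ...)
}

# noise-free configuration: every fish lies exactly on the VBGF curve and
# on W = a L^b
noise_free_config <- function(seed = 1, fish_per_reef = 20) {
  sp <- default_species_specs()
  for (s in names(sp)) {
    sp[[s]]$weight_sigma[] <- 0
    sp[[s]]$length_sigma <- 0
  }
  sim_config(seed = seed, fish_per_reef = fish_per_reef, species = sp)
}

# diet configuration with identical profiles in every zone (null case)
null_diet_config <- function(seed = 1, fish_per_reef = 6) {
  diet <- default_diet_specs()
  for (s in names(diet$alpha)) {
    a <- diet$alpha[[s]]
    a[] <- rep(colMeans(a), each = nrow(a))
    diet$alpha[[s]] <- a
  }
  sim_config(seed = seed, fish_per_reef = fish_per_reef, diet = diet)
}

# published zone-specific VBGF parameter sets (mm, 1/yr, yr) with the
# integer age ranges observed for each species
vbgf_reference_sets <- function() {
  list(
    browser_inner     = list(linf = 110.47, k = 0.19, t0 = -2, ages = 3:9),
    browser_disturbed = list(linf = 102.27, k = 0.17, t0 = -2, ages = 3:9),
    browser_outer     = list(linf = 97.86,  k = 0.23, t0 = -2, ages = 3:9),
    predator_inner    = list(linf = 125.23, k = 0.19, t0 = -2, ages = 3:8),
    predator_disturbed = list(linf = 102.04, k = 0.36, t0 = -2, ages = 3:8),
    predator_outer    = list(linf = 100.28, k = 0.30, t0 = -2, ages = 3:8)
  )
}

# independent one-way PERMANOVA pseudo-F, written directly from the sum
# of squares definitions (kept separate from the package implementation
# so it can serve as an oracle)
oracle_permanova_f <- function(dmat, grouping) {
  d2 <- as.matrix(dmat)^2
  n <- nrow(d2)
  lev <- unique(grouping)
  g <- length(lev)
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (l in lev) {
    i <- which(grouping == l)
    ss_w <- ss_w + sum(d2[i, i][upper.tri(d2[i, i])]) / length(i)
  }
  ((ss_tot - ss_w) / (g - 1)) / (ss_w / (n - g))
}
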