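#' Default species specifications for the synthetic generator
#'
#' Two benthic-feeding study species are emulated: a browsing corallivore
#' (butterflyfish-like, `"browser"`) and an active invertebrate predator
#' (hamlet-like, `"predator"`). Growth parameters are zone-specific von
#' Bertalanffy sets; condition noise is the SD of multiplicative lognormal
#' weight noise, allowed to differ by zone so that condition *variability*
#' (not just its mean) can respond to degradation. The browser's weight
#' noise is doubled in the disturbed zone, emulating the strongly inflated
#' condition variance observed on degraded reefs.
#'
#' @param zones Character vector of zone labels, ordered from highest to
#'   lowest coral cover.
#' @return Named list (one element per species) of species specifications.
#' @export
default_species_specs <- function(zones = default_zones()) {
  stopifnot(length(zones) == 3L)
  list(
    browser = list(
      allometry = list(a = 2e-5, b = 3),
      weight_sigma = stats::setNames(c(0.05, 0.05, 0.10), zones),
      length_sigma = 3,
      ages = 3:9,
      vbgf = data.frame(
        zone = zones,
        linf = c(97.86, 110.47, 102.27),
        k    = c(0.23, 0.19, 0.17),
        t0   = c(-2, -2, -2)
      ),
      depth = list(meanlog = log(25000), sdlog = 0.5)
    ),
    predator = list(
      allometry = list(a = 2e-5, b = 3),
      weight_sigma = stats::setNames(c(0.05, 0.05, 0.05), zones),
      length_sigma = 3,
      ages = 3:8,
      vbgf = data.frame(
        zone = zones,
        linf = c(100.28, 125.23, 102.04),
        k    = c(0.30, 0.19, 0.36),
        t0   = c(-2, -2, -2)
      ),
      depth = list(meanlog = log(6000), sdlog = 0.5)
    )
  )
}

#' @rdname default_species_specs
#' @export
default_zones <- function() {
  c("outer_bay", "inner_bay", "inner_bay_disturbed")
}

#' Default dietary Dirichlet profiles
#'
#' Per species, a matrix of Dirichlet concentration parameters (zones x
#' prey taxa) plus a taxonomy table for the prey. The browser moves from an
#' anthozoan-dominated profile in the outer bay to an annelid-dominated one
#' in the disturbed zone; the predator moves from benthic macrocrustaceans
#' (outer bay) to planktonic copepods (inside the bay). Profiles are
#' illustrative: the source study reports zone-level dominance patterns,
#' not per-taxon proportions.
#'
#' @inheritParams default_species_specs
#' @return Named list with elements `alpha` (list of zone x taxon
#'   concentration matrices per species) and `taxonomy` (data frame with
#'   columns `otu_id`, `phylum`, `class`, `order`, `family`, `genus`).
#' @export
default_diet_specs <- function(zones = default_zones()) {
  stopifnot(length(zones) == 3L)
  browser_taxa <- c("Porites_sp", "Plexaurella_sp", "Aiptasia_sp",
                    "Mussidae_sp", "Loimia_medusa", "Serpulidae_sp",
                    "Harpacticoida_sp", "Cerithium_sp")
  predator_taxa <- c("Mithraculus_sp", "Leptochelia_sp", "Pseudosquilla_sp",
                     "Synalpheus_sp", "Temora_stylifera", "Calanoida_sp",
                     "Coryphopterus_sp", "Emblemariopsis_sp")
  a_browser <- rbind(
    c(8.0, 2.5, 0.8, 0.7, 1.2, 0.8, 0.5, 0.5),  # outer: anthozoan-dominated
    c(4.5, 0.3, 2.2, 0.8, 4.5, 1.2, 0.8, 0.7),  # inner: mixed
    c(0.8, 0.1, 1.8, 1.3, 8.0, 1.5, 0.8, 0.7)   # disturbed: annelid-dominated
  )
  a_predator <- rbind(
    c(7.0, 1.5, 1.2, 0.8, 0.8, 0.5, 1.5, 0.7),  # outer: benthic arthropods
    c(1.2, 0.8, 0.5, 0.5, 6.5, 1.5, 1.6, 0.6),  # inner: planktonic copepods
    c(0.8, 0.7, 0.4, 0.4, 7.5, 1.8, 1.5, 0.6)
  )
  dimnames(a_browser) <- list(zones, browser_taxa)
  dimnames(a_predator) <- list(zones, predator_taxa)
  taxonomy <- data.frame(
    otu_id = c(browser_taxa, predator_taxa),
    phylum = c("Cnidaria", "Cnidaria", "Cnidaria", "Cnidaria",
               "Annelida", "Annelida", "Arthropoda", "Mollusca",
               "Arthropoda", "Arthropoda", "Arthropoda", "Arthropoda",
               "Arthropoda", "Arthropoda", "Chordata", "Chordata"),
    class = c("Anthozoa", "Anthozoa", "Anthozoa", "Anthozoa",
              "Polychaeta", "Polychaeta", "Copepoda", "Gastropoda",
              "Malacostraca", "Malacostraca", "Malacostraca",
              "Malacostraca", "Copepoda", "Copepoda",
              "Actinopterygii", "Actinopterygii"),
    order = c("Scleractinia", "Alcyonacea", "Actiniaria", "Scleractinia",
              "Terebellida", "Sabellida", "Harpacticoida",
              "Caenogastropoda", "Decapoda", "Tanaidacea", "Stomatopoda",
              "Decapoda", "Calanoida", "Calanoida", "Gobiiformes",
              "Blenniiformes"),
    family = c("Poritidae", "Plexauridae", "Aiptasiidae", "Mussidae",
               "Terebellidae", "Serpulidae", "unassigned", "Cerithiidae",
               "Mithracidae", "Leptocheliidae", "Pseudosquillidae",
               "Alpheidae", "Temoridae", "unassigned", "Gobiidae",
               "Chaenopsidae"),
    genus = c("Porites", "Plexaurella", "Aiptasia", "unassigned",
              "Loimia", "unassigned", "unassigned", "Cerithium",
              "Mithraculus", "Leptochelia", "Pseudosquilla", "Synalpheus",
              "Temora", "unassigned", "Coryphopterus", "Emblemariopsis"),
    stringsAsFactors = FALSE
  )
  list(alpha = list(browser = a_browser, predator = a_predator),
       taxonomy = taxonomy)
}

#' Default benthic, coral-cover and invertebrate survey specifications
#'
#' Zone mean/SD percent live hard coral cover (reef-level variation), the
#' relative weights of non-coral benthic categories, and per-quadrat
#' Poisson rates for mobile macroinvertebrate taxa (0.25 m2 rubble
#' quadrats).
#'
#' @inheritParams default_species_specs
#' @return List with elements `cover` (data frame: zone, mean, sd),
#'   `benthic_weights` (named vector over non-coral categories) and
#'   `invert_rates` (zone x taxon matrix of Poisson means per quadrat).
#' @export
default_survey_specs <- function(zones = default_zones()) {
  stopifnot(length(zones) == 3L)
  cover <- data.frame(zone = zones,
                      mean = c(33.46, 12.06, 0.34),
                      sd = c(3.41, 2.30, 0.39))
  benthic_weights <- c(soft_coral = 0.08, macroalgae = 0.25, sponge = 0.15,
                       dead_coral = 0.30, rubble = 0.17, zoanthid = 0.05)
  invert_rates <- rbind(
    c(decapods = 9, amphipods = 6, polychaetes = 5, gastropods = 4, ophiuroids = 3),
    c(decapods = 7, amphipods = 5, polychaetes = 5, gastropods = 3, ophiuroids = 2),
    c(decapods = 3, amphipods = 4, polychaetes = 4, gastropods = 2, ophiuroids = 1)
  )
  rownames(invert_rates) <- zones
  # belt-transect fish counts (100 m2): density peaks at the inner bay
  fish_rates <- cbind(browser = c(7, 9, 6), predator = c(2, 6, 4))
  rownames(fish_rates) <- zones
  list(cover = cover, benthic_weights = benthic_weights,
       invert_rates = invert_rates, fish_rates = fish_rates)
}

#' Simulation configuration for the zone-structured study design
#'
#' Bundles and validates every parameter of the synthetic generator. The
#' defaults reproduce the study conditions the analysis assumes: two
#' species, three habitat zones (high, intermediate and near-zero coral
#' cover), three replicate reefs per zone, 20 fish per reef and species,
#' integer otolith ages, zone-specific von Bertalanffy growth, allometric
#' weight with lognormal noise, Dirichlet-multinomial diet read profiles
#' with lognormal sequencing depths, 100-point photo quadrats and Poisson
#' invertebrate counts.
#'
#' @param seed Integer seed; all generator stages derive named substreams
#'   from it (see Details).
#' @param zones Zone labels, ordered high to low coral cover.
#' @param reefs_per_zone Number of replicate reefs per zone (>= 1).
#' @param fish_per_reef Fish collected per reef per species (>= 1).
#' @param species Species specifications, see [default_species_specs()].
#' @param diet Diet specifications, see [default_diet_specs()].
#' @param surveys Survey specifications, see [default_survey_specs()].
#' @param transects_per_reef,quadrats_per_transect Benthic survey layout
#'   (photo quadrats with a 100-point grid each).
#' @param invert_quadrats_per_reef Invertebrate rubble quadrats per reef.
#'
#' @details Reproducibility uses a single global seed split into named
#'   substreams, one per stage (`fish`, `diet`, `surveys`), so each stage
#'   can be re-run independently yet deterministically:
#'   `substream = (seed * 7919 + offset * 104729) mod (2^31 - 1)`.
#'
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       zones = default_zones(),
                       reefs_per_zone = 3L,
                       fish_per_reef = 20L,
                       species = default_species_specs(zones),
                       diet = default_diet_specs(zones),
                       surveys = default_survey_specs(zones),
                       transects_per_reef = 3L,
                       quadrats_per_transect = 10L,
                       invert_quadrats_per_reef = 3L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (reefs_per_zone < 1 || fish_per_reef < 1 || length(zones) < 1)
    stop("zone, reef and fish counts must all be >= 1", call. = FALSE)
  for (sp in names(species)) {
    s <- species[[sp]]
    if (s$allometry$a <= 0 || s$allometry$b <= 0)
      stop("allometry parameters must be positive for species '", sp, "'",
           call. = FALSE)
    if (any(s$weight_sigma < 0) || s$length_sigma < 0)
      stop("noise scales must be non-negative for species '", sp, "'",
           call. = FALSE)
    if (!all(zones %in% s$vbgf$zone))
      stop("missing VBGF parameters for some zones, species '", sp, "'",
           call. = FALSE)
    if (any(s$vbgf$linf <= 0) || any(s$vbgf$k <= 0))
      stop("VBGF scale parameters must be positive for species '", sp, "'",
           call. = FALSE)
  }
  for (sp in names(diet$alpha)) {
    a <- diet$alpha[[sp]]
    if (!all(zones %in% rownames(a)))
      stop("diet profile rows must cover every zone (species '", sp, "')",
           call. = FALSE)
    if (any(a <= 0))
      stop("Dirichlet concentrations must be strictly positive (species '",
           sp, "')", call. = FALSE)
  }
  if (!all(unlist(lapply(diet$alpha, colnames)) %in% diet$taxonomy$otu_id))
    stop("every prey taxon needs a taxonomy entry", call. = FALSE)
  structure(
    list(seed = as.integer(seed), zones = zones,
         reefs_per_zone = as.integer(reefs_per_zone),
         fish_per_reef = as.integer(fish_per_reef),
         species = species, diet = diet, surveys = surveys,
         transects_per_reef = as.integer(transects_per_reef),
         quadrats_per_transect = as.integer(quadrats_per_transect),
         invert_quadrats_per_reef = as.integer(invert_quadrats_per_reef)),
    class = "sim_config")
}

# named substream of the global seed; keeps stages independently re-runnable
substream_seed <- function(seed, stage) {
  offset <- c(fish = 1, diet = 2, surveys = 3)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647)
}

reef_labels <- function(config) {
  unlist(lapply(seq_along(config$zones), function(i)
    paste0("Z", i, "R", seq_len(config$reefs_per_zone))))
}

#' Simulate fish morphometric records
#'
#' Draws one record per fish: an integer age uniform on the species age
#' range, a total length from the zone-specific von Bertalanffy prediction
#' plus Gaussian noise, and a wet weight `W = a * L^b * exp(e)` with
#' `e ~ N(0, sigma^2)` (sigma possibly zone-specific). Deterministic for a
#' fixed config seed.
#'
#' @param config A [sim_config()] object.
#' @return Data frame with columns `id`, `species`, `zone`, `reef`,
#'   `length_mm`, `weight_g`, `age_yr`.
#' @export
simulate_fish <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "fish"))
  out <- list()
  for (sp in names(config$species)) {
    s <- config$species[[sp]]
    for (zi in seq_along(config$zones)) {
      zone <- config$zones[zi]
      pars <- s$vbgf[s$vbgf$zone == zone, , drop = FALSE]
      for (ri in seq_len(config$reefs_per_zone)) {
        reef <- paste0("Z", zi, "R", ri)
        n <- config$fish_per_reef
        age <- sample(s$ages, n, replace = TRUE)
        len <- vbgf_predict(age, pars$linf, pars$k, pars$t0) +
          rnorm(n, sd = s$length_sigma)
        len <- pmax(len, 1)
        w <- s$allometry$a * len^s$allometry$b *
          exp(rnorm(n, sd = s$weight_sigma[[zone]]))
        out[[length(out) + 1L]] <- data.frame(
          id = paste(sp, reef, seq_len(n), sep = "_"),
          species = sp, zone = zone, reef = reef,
          length_mm = len, weight_g = w, age_yr = age,
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate dietary metabarcoding read counts
#'
#' For each fish, a diet composition is drawn from the species-by-zone
#' Dirichlet profile, a sequencing depth from the species lognormal depth
#' distribution (rounded to an integer, floor 1), and reads from a
#' multinomial. The Dirichlet-multinomial captures the overdispersed
#' compositional structure of metabarcoding read tables.
#'
#' @param config A [sim_config()] object.
#' @param fish Fish table from [simulate_fish()].
#' @return List with `counts` (samples x OTU integer matrix, rownames =
#'   fish ids) and `taxonomy` (OTU lineage data frame).
#' @export
simulate_diet_reads <- function(config, fish) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "diet"))
  taxa_all <- unique(unlist(lapply(config$diet$alpha, colnames)))
  counts <- matrix(0L, nrow = nrow(fish), ncol = length(taxa_all),
                   dimnames = list(fish$id, taxa_all))
  for (i in seq_len(nrow(fish))) {
    sp <- fish$species[i]
    alpha <- config$diet$alpha[[sp]]
    if (is.null(alpha))
      stop("no diet profile for species '", sp, "'", call. = FALSE)
    a <- alpha[fish$zone[i], ]
    g <- rgamma(length(a), shape = a)
    if (all(g == 0)) g[which.max(a)] <- 1  # numerical underflow guard
    p <- g / sum(g)
    depth <- max(1L, as.integer(round(rlnorm(1,
      config$species[[sp]]$depth$meanlog, config$species[[sp]]$depth$sdlog))))
    counts[i, colnames(alpha)] <- as.integer(rmultinom(1, depth, p))
  }
  taxonomy <- config$diet$taxonomy[
    config$diet$taxonomy$otu_id %in% taxa_all, , drop = FALSE]
  rownames(taxonomy) <- NULL
  list(counts = counts, taxonomy = taxonomy)
}

#' Simulate benthic, invertebrate and fish-transect surveys
#'
#' Benthic photo quadrats receive 100 point counts multinomially over
#' benthic categories, with a reef-level expected live-coral fraction drawn
#' from the zone mean/SD (truncated to \[0, 100\]); the non-coral remainder
#' is split by fixed category weights. Invertebrate counts are Poisson per
#' taxon per 0.25 m2 quadrat; belt-transect fish counts are Poisson per
#' species per 100 m2 transect.
#'
#' @param config A [sim_config()] object.
#' @return List with data frames `benthic` (zone, reef, transect, quadrat,
#'   one column per category, rows sum to 100), `inverts` (zone, reef,
#'   quadrat, one column per taxon) and `fish_transects` (zone, reef,
#'   transect, one column per species).
#' @export
simulate_surveys <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "surveys"))
  sv <- config$surveys
  w <- sv$benthic_weights
  if (sum(w) <= 0) stop("benthic category weights must sum > 0", call. = FALSE)
  w <- w / sum(w)
  benthic <- list(); inverts <- list(); fishtr <- list()
  for (zi in seq_along(config$zones)) {
    zone <- config$zones[zi]
    cover_row <- sv$cover[sv$cover$zone == zone, ]
    for (ri in seq_len(config$reefs_per_zone)) {
      reef <- paste0("Z", zi, "R", ri)
      coral_frac <- min(max(rnorm(1, cover_row$mean, cover_row$sd), 0), 100) / 100
      if (cover_row$mean == 0 && cover_row$sd == 0) coral_frac <- 0
      probs <- c(hard_coral = coral_frac, w * (1 - coral_frac))
      for (ti in seq_len(config$transects_per_reef)) {
        for (qi in seq_len(config$quadrats_per_transect)) {
          pts <- as.integer(rmultinom(1, 100, probs))
          benthic[[length(benthic) + 1L]] <- data.frame(
            zone = zone, reef = reef, transect = ti, quadrat = qi,
            as.list(stats::setNames(pts, names(probs))),
            stringsAsFactors = FALSE)
        }
        fishtr[[length(fishtr) + 1L]] <- data.frame(
          zone = zone, reef = reef, transect = ti,
          as.list(stats::setNames(
            rpois(ncol(sv$fish_rates), sv$fish_rates[zone, ]),
            colnames(sv$fish_rates))),
          stringsAsFactors = FALSE)
      }
      for (qi in seq_len(config$invert_quadrats_per_reef)) {
        inverts[[length(inverts) + 1L]] <- data.frame(
          zone = zone, reef = reef, quadrat = qi,
          as.list(stats::setNames(
            rpois(ncol(sv$invert_rates), sv$invert_rates[zone, ]),
            colnames(sv$invert_rates))),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(benthic = do.call(rbind, benthic),
       inverts = do.call(rbind, inverts),
       fish_transects = do.call(rbind, fishtr))
}

#' Simulate a complete synthetic dataset
#'
#' Runs all generator stages and returns every table together with the
#' generating configuration (the immutable "truth" block).
#'
#' @param config A [sim_config()] object.
#' @return Object of class `synthetic_dataset`: list with `fish`, `otu`
#'   (counts matrix), `taxonomy`, `benthic`, `inverts`, `fish_transects`
#'   and `truth` (the config).
#' @export
simulate_dataset <- function(config = sim_config()) {
  fish <- simulate_fish(config)
  diet <- simulate_diet_reads(config, fish)
  surveys <- simulate_surveys(config)
  structure(list(fish = fish, otu = diet$counts, taxonomy = diet$taxonomy,
                 benthic = surveys$benthic, inverts = surveys$inverts,
                 fish_transects = surveys$fish_transects, truth = config),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic reef-fish dataset (seed ", x$truth$seed, ")\n", sep = "")
  cat("  fish records: ", nrow(x$fish), " (",
      length(unique(x$fish$species)), " species, ",
      length(x$truth$zones), " zones, ",
      length(unique(x$fish$reef)), " reefs)\n", sep = "")
  cat("  OTU table: ", nrow(x$otu), " samples x ", ncol(x$otu), " OTUs\n",
      sep = "")
  cat("  benthic quadrats: ", nrow(x$benthic),
      "; invertebrate quadrats: ", nrow(x$inverts), "\n", sep = "")
  invisible(x)
}
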