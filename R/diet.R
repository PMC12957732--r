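#' Aggregate an OTU table at a taxonomic rank
#'
#' Sums reads per sample across OTUs sharing the same label at the
#' requested rank. OTUs unassigned at that rank (missing, `NA`, `""` or
#' `"unassigned"`) are pooled into an explicit `"unassigned"` column.
#' Total reads are conserved at every rank.
#'
#' @param x Numeric matrix, samples x OTUs (column names = OTU ids).
#' @param taxonomy Data frame with column `otu_id` plus rank columns.
#' @param rank One of the rank columns, e.g. `"phylum"` or `"genus"`.
#' @return Numeric matrix, samples x taxa at the requested rank.
#' @export
aggregate_taxa <- function(x, taxonomy, rank) {
  x <- as.matrix(x)
  ranks <- setdiff(names(taxonomy), "otu_id")
  if (!rank %in% ranks)
    stop("unknown rank '", rank, "'; available: ",
         paste(ranks, collapse = ", "), call. = FALSE)
  hit <- match(colnames(x), taxonomy$otu_id)
  if (anyNA(hit))
    stop("OTU(s) missing from the taxonomy table: ",
         paste(colnames(x)[is.na(hit)], collapse = ", "), call. = FALSE)
  lab <- as.character(taxonomy[[rank]][hit])
  lab[is.na(lab) | lab == ""] <- "unassigned"
  agg <- t(rowsum(t(x), group = lab))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Relative abundance table
#'
#' Divides each sample (row) by its total so that rows sum to 1.
#'
#' @param x Numeric matrix, samples x taxa; no all-zero rows.
#' @return Matrix of proportions.
#' @export
relative_abundance <- function(x) {
  x <- as.matrix(x)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  x / rs
}

#' Presence-absence table
#'
#' Binarises a count table at a minimum read threshold.
#'
#' @param x Numeric matrix, samples x taxa.
#' @param min_reads Counts >= `min_reads` become 1 (default 1).
#' @return Binary 0/1 matrix.
#' @export
presence_absence <- function(x, min_reads = 1) {
  x <- as.matrix(x)
  (x >= min_reads) * 1
}

#' Sample-based rarefaction curve
#'
#' Expected OTU richness as a function of the number of samples drawn
#' (without replacement) from a group. For each subset size `s`, the mean
#' and SD of richness are taken over all `choose(n, s)` subsets when that
#' number does not exceed `n_draws` (exhaustive enumeration, exact), and
#' over `n_draws` random subsets otherwise.
#'
#' @param x Numeric matrix, samples x OTUs, for one group; or supply
#'   `groups` to get one curve per group.
#' @param groups Optional grouping vector over rows of `x`.
#' @param n_draws Random subsets per size when enumeration is infeasible
#'   (default 200).
#' @param seed Optional integer seed.
#' @return Data frame with columns `group` (if grouped), `s`,
#'   `mean_richness`, `sd_richness`, `exact` (logical: enumerated?).
#' @export
rarefaction_curve <- function(x, groups = NULL, n_draws = 200, seed = NULL) {
  x <- as.matrix(x)
  if (!is.null(seed)) set.seed(seed)
  one_group <- function(m, label = NULL) {
    n <- nrow(m)
    if (n < 2) stop("need at least 2 samples per group", call. = FALSE)
    out <- lapply(seq_len(n), function(s) {
      n_comb <- choose(n, s)
      if (n_comb <= n_draws) {
        subsets <- combn(n, s, simplify = FALSE)
        exact <- TRUE
      } else {
        subsets <- replicate(n_draws, sample.int(n, s), simplify = FALSE)
        exact <- FALSE
      }
      rich <- vapply(subsets, function(idx)
        sum(colSums(m[idx, , drop = FALSE]) > 0), numeric(1))
      data.frame(s = s, mean_richness = mean(rich),
                 sd_richness = if (length(rich) > 1) sd(rich) else 0,
                 exact = exact)
    })
    res <- do.call(rbind, out)
    if (!is.null(label)) res <- cbind(group = label, res)
    res
  }
  if (is.null(groups)) return(one_group(x))
  stopifnot(length(groups) == nrow(x))
  do.call(rbind, lapply(unique(groups), function(g)
    one_group(x[groups == g, , drop = FALSE], label = g)))
}

#' Amundsen-Costello feeding-strategy analysis
#'
#' For each prey (OTU or aggregated taxon): the frequency of occurrence
#' `FO = 100 * (fish containing the prey) / (all fish)` and the
#' prey-specific abundance `P_i = 100 * sum(S_i) / sum(S_ti)`, where `S_i`
#' is the abundance of prey i and `S_ti` the total prey abundance, both
#' summed over only those fish that contain prey i. With relative read
#' abundances (the default, recommended for metabarcoding) `P_i` is the
#' mean relative read abundance of the prey among the fish containing it.
#' Prey plotted in the upper right are population-level specialisations;
#' lower left are rare, occasional items; high-P/low-FO points indicate a
#' between-phenotype (BPC) niche component, low-P/high-FO a
#' within-phenotype (WPC) component.
#'
#' @param x Numeric count matrix, samples (fish) x prey.
#' @param abundance `"relative"` (per-fish proportions, default) or
#'   `"raw"` (counts as given).
#' @param min_reads Minimum reads for a prey to count as present.
#' @param fo_threshold,pi_threshold Quadrant thresholds in percent
#'   (defaults 50/50).
#' @return Data frame (class `amundsen`) with `prey`, `fo`, `pi`,
#'   `quadrant` (one of `"dominant-specialized"`, `"rare-occasional"`,
#'   `"BPC-leaning"`, `"WPC-leaning"`); prey never observed are excluded.
#'   The quadrant counts are attached as `attr(, "summary")`.
#' @export
amundsen <- function(x, abundance = c("relative", "raw"), min_reads = 1,
                     fo_threshold = 50, pi_threshold = 50) {
  abundance <- match.arg(abundance)
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("empty table", call. = FALSE)
  ab <- if (abundance == "relative") relative_abundance(x) else x
  present <- x >= min_reads
  fo <- 100 * colMeans(present)
  pi <- vapply(seq_len(ncol(x)), function(j) {
    idx <- present[, j]
    if (!any(idx)) return(NA_real_)
    100 * sum(ab[idx, j]) / sum(ab[idx, , drop = FALSE])
  }, numeric(1))
  keep <- fo > 0
  fo <- fo[keep]; pi <- pi[keep]
  prey <- colnames(x)[keep]
  quadrant <- ifelse(fo >= fo_threshold & pi >= pi_threshold,
                     "dominant-specialized",
              ifelse(fo < fo_threshold & pi < pi_threshold,
                     "rare-occasional",
              ifelse(pi >= pi_threshold, "BPC-leaning", "WPC-leaning")))
  out <- data.frame(prey = prey, fo = unname(fo), pi = unname(pi),
                    quadrant = quadrant, stringsAsFactors = FALSE)
  out <- out[order(-out$pi), ]
  rownames(out) <- NULL
  attr(out, "summary") <- table(factor(out$quadrant,
    levels = c("dominant-specialized", "rare-occasional",
               "BPC-leaning", "WPC-leaning")))
  class(out) <- c("amundsen", "data.frame")
  out
}

#' Default planktonic/benthic habit lookup for arthropod prey
#'
#' Assigns the commonly encountered arthropod prey genera to a planktonic
#' or benthic habit; used to aggregate the predator's diet into the two
#' crustacean response groups of the coral-cover models.
#'
#' @return Data frame with columns `genus`, `habit`.
#' @export
default_habit_lookup <- function() {
  data.frame(
    genus = c("Temora", "Calanoida", "Acartia", "Oithona",
              "Mithraculus", "Leptochelia", "Pseudosquilla", "Sicyonia",
              "Panoplax", "Synalpheus", "Neogonodactylus"),
    habit = c("planktonic", "planktonic", "planktonic", "planktonic",
              "benthic", "benthic", "benthic", "benthic",
              "benthic", "benthic", "benthic"),
    stringsAsFactors = FALSE)
}

#' Negative-binomial mixed model of prey read abundance
#'
#' Tests whether a predictor (reef-level percent coral cover, or fish
#' age) affects the sequencing read abundance of a prey group, with
#' random intercepts for the zone/reef hierarchy, using a
#' negative-binomial GLMM (log link, [glmmTMB::glmmTMB()]) and a
#' likelihood ratio test of the predictor against the null model
#' (`LRT = 2 * (llik_full - llik_null)`, p from chi-squared with 1 df).
#'
#' Two response modes are offered. `"offset"` (recommended) models the
#' raw prey counts with `log(depth)` as an offset, so that sequencing
#' effort is handled inside the count model. `"mimic"` applies a variance
#' stabilising transformation to the counts (square root, fourth root or
#' log1p) and rounds to the nearest integer before the NB fit; this mode
#' reproduces a transformation-based workflow sometimes used in practice
#' and is clearly labelled in the result.
#'
#' @param counts Integer vector of prey reads per fish.
#' @param predictor Numeric vector (coral cover %, or age), per fish.
#' @param zone,reef Grouping vectors per fish.
#' @param depth Total reads per fish (required for `mode = "offset"`).
#' @param random `"zone_reef"` (reef nested in zone, default) or
#'   `"zone"` (used for the hard-coral response, whose availability is
#'   collinear with coral cover).
#' @param mode `"offset"` or `"mimic"`.
#' @param transform For `mode = "mimic"`: `"none"`, `"sqrt"`,
#'   `"fourth_root"` or `"log"` (log1p).
#' @param labels Optional named character vector (`response`,
#'   `predictor`) carried into the result.
#' @return Object of class `prey_glmm`: list with `estimate` (predictor
#'   coefficient, log scale), `se`, `chisq`, `df = 1`, `p`, `converged`,
#'   `mode`, `transform`, `random`, `labels`, and the fitted `full` and
#'   `null` models.
#' @export
fit_prey_glmm <- function(counts, predictor, zone, reef, depth = NULL,
                          random = c("zone_reef", "zone"),
                          mode = c("offset", "mimic"),
                          transform = c("none", "sqrt", "fourth_root", "log"),
                          labels = NULL) {
  random <- match.arg(random)
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  n <- length(counts)
  stopifnot(length(predictor) == n, length(zone) == n, length(reef) == n)
  if (any(counts < 0)) stop("negative counts", call. = FALSE)
  if (stats::var(predictor) == 0)
    stop("predictor does not vary", call. = FALSE)
  dat <- data.frame(y = counts, pred = predictor,
                    zone = factor(zone), reef = factor(reef))
  if (mode == "offset") {
    if (is.null(depth)) stop("mode = 'offset' requires depth", call. = FALSE)
    stopifnot(length(depth) == n)
    dat$off <- log(depth)
  } else {
    dat$y <- switch(transform,
                    none = dat$y,
                    sqrt = round(sqrt(dat$y)),
                    fourth_root = round(dat$y^0.25),
                    log = round(log1p(dat$y)))
  }
  re <- if (random == "zone_reef") "(1 | zone / reef)" else "(1 | zone)"
  off <- if (mode == "offset") " + offset(off)" else ""
  f_full <- as.formula(paste0("y ~ pred + ", re, off))
  f_null <- as.formula(paste0("y ~ 1 + ", re, off))
  fit_one <- function(f) {
    suppressWarnings(glmmTMB::glmmTMB(f, data = dat,
                                      family = glmmTMB::nbinom2()))
  }
  full <- fit_one(f_full)
  null <- fit_one(f_null)
  ok <- function(m) isTRUE(m$sdr$pdHess) && !isTRUE(m$fit$convergence != 0)
  lrt <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  sm <- summary(full)$coefficients$cond
  structure(list(estimate = unname(sm["pred", "Estimate"]),
                 se = unname(sm["pred", "Std. Error"]),
                 chisq = lrt, df = 1L,
                 p = pchisq(lrt, df = 1, lower.tail = FALSE),
                 converged = ok(full) && ok(null),
                 mode = mode, transform = transform, random = random,
                 labels = labels, full = full, null = null),
            class = "prey_glmm")
}

#' @export
print.prey_glmm <- function(x, ...) {
  lab <- if (!is.null(x$labels))
    paste0(" [", paste(names(x$labels), x$labels, sep = ": ",
                       collapse = ", "), "]") else ""
  cat("NB mixed model", lab, " (mode = ", x$mode,
      if (x$mode == "mimic") paste0(", transform = ", x$transform) else "",
      ", random = ", x$random, ")\n", sep = "")
  cat("  slope = ", signif(x$estimate, 4), " (SE ", signif(x$se, 4),
      "), LRT chi2(1) = ", signif(x$chisq, 4), ", p = ", signif(x$p, 4),
      if (!x$converged) "  [convergence not verified]" else "",
      "\n", sep = "")
  invisible(x)
}
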