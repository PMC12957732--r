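#' Kruskal-Wallis test with rank epsilon squared
#'
#' Tie-corrected Kruskal-Wallis H with p from the chi-squared reference
#' and the rank-based effect size `epsilon^2 = H * (n + 1) / (n^2 - 1)`.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector, same length; >= 2 non-empty groups and
#'   total n >= 5.
#' @return Object of class `group_test`: list with `statistic` (H), `df`,
#'   `p`, `effect_size` (epsilon squared), `method`.
#' @export
kruskal_epsilon <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(droplevels(g)) < 2 || any(table(droplevels(g)) == 0))
    stop("need at least 2 non-empty groups", call. = FALSE)
  n <- length(values)
  if (n < 5) stop("need total n >= 5", call. = FALSE)
  if (length(unique(values)) == 1) {
    # all observations tied: no rank variation, H defined as 0
    return(structure(list(statistic = 0, df = nlevels(g) - 1L, p = 1,
                          effect_size = 0,
                          effect_size_name = "epsilon_squared",
                          method = "Kruskal-Wallis"),
                     class = "group_test"))
  }
  kt <- kruskal.test(values, g)
  h <- unname(kt$statistic)
  structure(list(statistic = h, df = unname(kt$parameter),
                 p = kt$p.value,
                 effect_size = h * (n + 1) / (n^2 - 1),
                 effect_size_name = "epsilon_squared",
                 method = "Kruskal-Wallis"),
            class = "group_test")
}

#' Dunn's post hoc test on mean ranks
#'
#' Pairwise Z statistics on group mean ranks with the tie-corrected
#' pooled rank variance, two-sided p-values, and Benjamini-Hochberg
#' (default) adjustment across all pairs.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (>= 2 groups).
#' @param adjust Adjustment method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return Data frame: `group1`, `group2`, `z`, `p`, `p_adjusted`,
#'   `adjustment`.
#' @export
dunn_posthoc <- function(values, groups, adjust = "BH") {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  n <- length(values)
  r <- rank(values)
  mean_ranks <- tapply(r, g, mean)
  sizes <- tapply(r, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  prs <- combn(levels(g), 2)
  out <- lapply(seq_len(ncol(prs)), function(j) {
    g1 <- prs[1, j]; g2 <- prs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[g1]] + 1 / sizes[[g2]]))
    z <- (mean_ranks[[g1]] - mean_ranks[[g2]]) / se
    data.frame(group1 = g1, group2 = g2, z = z,
               p = 2 * pnorm(-abs(z)), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p_adjusted <- p.adjust(res$p, method = adjust)
  res$adjustment <- adjust
  rownames(res) <- NULL
  res
}

#' One-way ANOVA with Tukey HSD post hoc
#'
#' Classical one-way F test with Tukey's honest significant differences
#' via the studentized range. When the residual variance is exactly zero
#' while group means differ, `F` is reported as `Inf` and flagged.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector; >= 2 groups, each with >= 2 values.
#' @return Object of class `group_test`: `statistic` (F), `df` (between,
#'   within), `p`, `effect_size` (partial eta squared for the group term)
#'   and `posthoc` (pair, diff, lwr, upr, p_adjusted).
#' @export
anova_tukey <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2 || any(table(g) < 2))
    stop("need >= 2 groups, each with >= 2 values", call. = FALSE)
  dat <- data.frame(y = values, g = g)
  fit <- aov(y ~ g, data = dat)
  an <- anova(fit)
  ss_g <- an[["Sum Sq"]][1]; ss_r <- an[["Sum Sq"]][2]
  degenerate <- ss_r <= .Machine$double.eps * max(ss_g, 1) && ss_g > 0
  f_stat <- if (degenerate) Inf else an[["F value"]][1]
  p <- if (degenerate) 0 else an[["Pr(>F)"]][1]
  if (ss_g == 0 && ss_r == 0) { f_stat <- 0; p <- 1 }  # all values equal
  tk <- TukeyHSD(fit)$g
  posthoc <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        lwr = tk[, "lwr"], upr = tk[, "upr"],
                        p_adjusted = tk[, "p adj"], row.names = NULL)
  structure(list(statistic = f_stat,
                 df = c(between = an$Df[1], within = an$Df[2]),
                 p = p, effect_size = ss_g / (ss_g + ss_r),
                 effect_size_name = "partial_eta_squared",
                 method = "one-way ANOVA", degenerate = degenerate,
                 posthoc = posthoc),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 5),
      ", df = ", paste(x$df, collapse = ", "),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  cat("  ", x$effect_size_name, " = ", signif(x$effect_size, 4), "\n",
      sep = "")
  if (!is.null(x$posthoc)) {
    cat("  post hoc:\n")
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

#' Shannon diversity (natural log)
#'
#' `H' = -sum(p_i * ln(p_i))` over categories with positive counts, in
#' nats. Maximised at `ln(richness)` by the uniform distribution.
#'
#' @param counts Non-negative numeric vector; total must be positive.
#' @return Shannon H' in nats.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (sum(counts) <= 0) stop("all-zero input", call. = FALSE)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Percent coral cover per reef and zone (two-stage mean)
#'
#' Per-quadrat live hard-coral percent (100-point grids make counts equal
#' percentages), averaged first over the quadrats of each transect and
#' then over the transects of each reef. Zone summaries report the mean
#' and SD over transect-level means, and the mean over reef means.
#'
#' @param benthic Data frame with columns `zone`, `reef`, `transect` and
#'   `hard_coral` (points out of 100 per quadrat).
#' @return List of data frames: `transect` (zone, reef, transect,
#'   percent), `reef` (zone, reef, mean_cover), `zone` (zone, mean_cover,
#'   sd_cover over transects, reef_mean_cover).
#' @export
coral_cover_summary <- function(benthic) {
  check_fish_columns(benthic, c("zone", "reef", "transect", "hard_coral"))
  tr <- aggregate(hard_coral ~ zone + reef + transect, data = benthic,
                  FUN = mean)
  names(tr)[names(tr) == "hard_coral"] <- "percent_cover"
  rf <- aggregate(percent_cover ~ zone + reef, data = tr, FUN = mean)
  names(rf)[names(rf) == "percent_cover"] <- "mean_cover"
  zn <- do.call(rbind, lapply(split(tr, tr$zone), function(s)
    data.frame(zone = s$zone[1], mean_cover = mean(s$percent_cover),
               sd_cover = sd(s$percent_cover))))
  zn$reef_mean_cover <- tapply(rf$mean_cover, rf$zone, mean)[zn$zone]
  rownames(zn) <- NULL
  list(transect = tr, reef = rf, zone = zn)
}

#' Densities per unit area with reef and zone summaries
#'
#' Converts replicate counts (belt transects or quadrats) into densities
#' (individuals per m2), then reports the mean and SD across replicates
#' within each reef and the mean across reef means within each zone.
#'
#' @param counts Data frame with columns `zone`, `reef`, a replicate
#'   column and one count column.
#' @param count_col Name of the count column.
#' @param area Sampled area per replicate in m2 (e.g. 100 for a 20 x 5 m
#'   belt; 0.25 for a 50 x 50 cm quadrat).
#' @return List of data frames: `replicate` (with `density`), `reef`
#'   (mean_density, sd_density), `zone` (mean_density across reef means).
#' @export
density_summary <- function(counts, count_col, area) {
  if (!is.numeric(area) || area <= 0)
    stop("area must be positive", call. = FALSE)
  check_fish_columns(counts, c("zone", "reef", count_col))
  rep_df <- counts[, c("zone", "reef", count_col)]
  rep_df$density <- counts[[count_col]] / area
  rf <- do.call(rbind, lapply(split(rep_df, rep_df$reef), function(s)
    data.frame(zone = s$zone[1], reef = s$reef[1],
               mean_density = mean(s$density),
               sd_density = sd(s$density))))
  zn <- do.call(rbind, lapply(split(rf, rf$zone), function(s)
    data.frame(zone = s$zone[1], mean_density = mean(s$mean_density),
               sd_density = sd(s$mean_density))))
  rownames(rf) <- rownames(zn) <- NULL
  list(replicate = rep_df, reef = rf, zone = zn)
}

#' @importFrom stats aggregate
NULL
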