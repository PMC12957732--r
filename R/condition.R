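#' Fit the length-weight allometry by log-log regression
#'
#' Ordinary least squares of `ln(W)` on `ln(L)` for one species, i.e. the
#' allometric model `W = a * L^b` on the log scale. The fitted intercept is
#' `ln(a)` and the slope is the allometric exponent `b`.
#'
#' @param fish Data frame with numeric columns `length_mm` and `weight_g`
#'   (strictly positive).
#' @return Object of class `lw_fit`: list with `log_a`, `b`, `a`, `n`,
#'   `sigma` (residual SD on the log scale), `se` (named vector of
#'   coefficient SEs) and the underlying `lm` fit.
#' @examples
#' fish <- data.frame(length_mm = c(60, 70, 80, 90),
#'                    weight_g = 2e-5 * c(60, 70, 80, 90)^3)
#' fit_length_weight(fish)
#' @export
fit_length_weight <- function(fish) {
  check_fish_columns(fish, c("length_mm", "weight_g"))
  if (nrow(fish) < 3)
    stop("need at least 3 fish to fit the length-weight relationship",
         call. = FALSE)
  if (any(fish$length_mm <= 0) || any(fish$weight_g <= 0))
    stop("lengths and weights must be strictly positive", call. = FALSE)
  if (length(unique(fish$length_mm)) < 2)
    stop("all lengths are equal: singular design", call. = FALSE)
  m <- lm(log(weight_g) ~ log(length_mm), data = fish)
  cf <- coef(m)
  structure(list(log_a = unname(cf[1]), b = unname(cf[2]),
                 a = exp(unname(cf[1])), n = nrow(fish),
                 sigma = summary(m)$sigma,
                 se = stats::setNames(summary(m)$coefficients[, "Std. Error"],
                                      c("log_a", "b")),
                 model = m),
            class = "lw_fit")
}

#' @export
print.lw_fit <- function(x, ...) {
  cat("Length-weight fit: ln W = ", signif(x$log_a, 6), " + ",
      signif(x$b, 6), " ln L  (n = ", x$n, ")\n", sep = "")
  cat("  a = ", signif(x$a, 6), " g/mm^b, residual SD (log) = ",
      signif(x$sigma, 4), "\n", sep = "")
  invisible(x)
}

#' Le Cren's relative condition factor
#'
#' `K_n = W / (a * L^b)` on the raw measurement scale, where `a` and `b`
#' come from the population length-weight regression. `K_n = 1` means the
#' fish has exactly the length-predicted mean weight; values above 1
#' indicate good condition ("plumpness"), below 1 suboptimal condition.
#' Because OLS log residuals sum to zero, the geometric mean of `K_n` over
#' the fitting sample is exactly 1.
#'
#' @param fish Data frame with columns `length_mm`, `weight_g` and
#'   (optionally) `id`, `zone`, `reef`, carried through.
#' @param fit A [fit_length_weight()] fit from the same population.
#' @return Data frame (class `condition_table`) with the carried columns
#'   plus `log_length` and `kn`.
#' @export
compute_kn <- function(fish, fit) {
  stopifnot(inherits(fit, "lw_fit"))
  check_fish_columns(fish, c("length_mm", "weight_g"))
  if (any(fish$length_mm <= 0))
    stop("lengths must be strictly positive", call. = FALSE)
  keep <- intersect(c("id", "species", "zone", "reef", "length_mm",
                      "weight_g", "age_yr"), names(fish))
  out <- fish[, keep, drop = FALSE]
  out$log_length <- log(fish$length_mm)
  out$kn <- fish$weight_g / (fit$a * fish$length_mm^fit$b)
  class(out) <- c("condition_table", "data.frame")
  out
}

#' Condition-by-zone interaction model
#'
#' Fits `K_n ~ log(L) * zone` by OLS and summarises it the way the
#' condition analysis requires: a sequential (Type I) ANOVA with partial
#' eta squared per term, per-zone marginal slopes of condition on log
#' length (via [emmeans::emtrends()]), and all pairwise slope contrasts
#' with Tukey-adjusted p-values.
#'
#' @param cond A [compute_kn()] table with at least 2 zones, each with 3+
#'   fish and 2+ distinct lengths.
#' @return Object of class `condition_interaction`: list with `model`,
#'   `anova` (term, df, sum_sq, mean_sq, f, p, partial_eta_sq), `slopes`
#'   (zone, slope, se, df, ci), `contrasts` (Tukey-adjusted pairwise slope
#'   differences) and `residuals` (per fish, with zone).
#' @export
fit_condition_interaction <- function(cond) {
  stopifnot(is.data.frame(cond))
  check_fish_columns(cond, c("kn", "log_length", "zone"))
  zones <- unique(cond$zone)
  if (length(zones) < 2)
    stop("need at least 2 zones", call. = FALSE)
  for (z in zones) {
    sub <- cond[cond$zone == z, ]
    if (nrow(sub) < 3 || length(unique(sub$log_length)) < 2)
      stop("zone '", z, "' needs >= 3 fish with >= 2 distinct lengths",
           call. = FALSE)
  }
  cond$zone <- factor(cond$zone)
  m <- lm(kn ~ log_length * zone, data = cond)
  an <- anova(m)
  ss <- an[["Sum Sq"]]
  ss_res <- ss[length(ss)]
  atab <- data.frame(term = rownames(an), df = an$Df, sum_sq = ss,
                     mean_sq = an[["Mean Sq"]], f = an[["F value"]],
                     p = an[["Pr(>F)"]],
                     partial_eta_sq = ss / (ss + ss_res),
                     row.names = NULL)
  atab$partial_eta_sq[atab$term == "Residuals"] <- NA_real_
  emm <- emmeans::emtrends(m, ~ zone, var = "log_length")
  slopes <- as.data.frame(summary(emm))
  names(slopes)[names(slopes) == "log_length.trend"] <- "slope"
  names(slopes)[names(slopes) == "SE"] <- "se"
  ctr <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))
  ctr_raw <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")))
  ctr$p_unadjusted <- ctr_raw$p.value
  names(ctr)[names(ctr) == "p.value"] <- "p_tukey"
  structure(list(model = m, anova = atab, slopes = slopes,
                 contrasts = ctr,
                 residuals = data.frame(zone = as.character(cond$zone),
                                        residual = unname(resid(m)))),
            class = "condition_interaction")
}

#' @export
print.condition_interaction <- function(x, ...) {
  cat("Condition ~ log(length) * zone\n\nSequential ANOVA:\n")
  print(x$anova, digits = 4)
  cat("\nMarginal slopes by zone:\n")
  print(x$slopes, digits = 4)
  cat("\nPairwise slope contrasts (Tukey-adjusted):\n")
  print(x$contrasts, digits = 4)
  invisible(x)
}

# lnVR point estimate between two groups, optionally with the
# small-sample bias correction 1/(2(n-1)) terms
lnvr_point <- function(x1, x2, bias_correction = TRUE) {
  s1 <- sd(x1); s2 <- sd(x2)
  if (s1 == 0 || s2 == 0)
    stop("zero variance in a group: lnVR undefined", call. = FALSE)
  out <- log(s1 / s2)
  if (bias_correction)
    out <- out + 1 / (2 * (length(x1) - 1)) - 1 / (2 * (length(x2) - 1))
  out
}

#' Pairwise log variance ratios with bootstrap confidence intervals
#'
#' For every pair of groups, computes the log variance ratio
#' `lnVR = ln(SD1/SD2) + 1/(2(n1-1)) - 1/(2(n2-1))` (the second and third
#' terms are a small-sample bias correction, on by default) and a
#' percentile bootstrap 95% CI from `B` case resamples drawn independently
#' within each group. A contrast is flagged significant when its CI
#' excludes zero. Typically applied to the residuals of the
#' condition-by-length model ([fit_condition_interaction()]) so that
#' variability is compared while controlling for fish size.
#'
#' @param values Numeric vector (e.g. model residuals).
#' @param groups Grouping vector (e.g. zone), same length.
#' @param B Number of bootstrap resamples (default 1000).
#' @param seed Optional integer seed for the bootstrap.
#' @param bias_correction Include the small-sample correction terms?
#' @param conf Confidence level (default 0.95).
#' @return Data frame (class `lnvr_table`): `group1`, `group2`, `lnvr`,
#'   `ci_lower`, `ci_upper`, `n1`, `n2`, `B`, `significant`.
#' @export
lnvr_pairwise <- function(values, groups, B = 1000, seed = NULL,
                          bias_correction = TRUE, conf = 0.95) {
  stopifnot(length(values) == length(groups), B >= 1)
  groups <- as.character(groups)
  levs <- unique(groups)
  if (length(levs) < 2) stop("need at least 2 groups", call. = FALSE)
  split_vals <- split(values, groups)
  if (any(vapply(split_vals, length, 1L) < 3))
    stop("each group needs n >= 3", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  boot_sds <- lapply(split_vals, function(x) {
    n <- length(x)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)
    xm <- matrix(x[idx], nrow = n)
    sqrt((colSums(xm^2) - n * colMeans(xm)^2) / (n - 1))
  })
  pairs <- combn(levs, 2)
  alpha <- (1 - conf) / 2
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    x1 <- split_vals[[g1]]; x2 <- split_vals[[g2]]
    est <- lnvr_point(x1, x2, bias_correction)
    s1 <- boot_sds[[g1]]; s2 <- boot_sds[[g2]]
    ok <- s1 > 0 & s2 > 0
    bl <- log(s1[ok] / s2[ok])
    if (bias_correction)
      bl <- bl + 1 / (2 * (length(x1) - 1)) - 1 / (2 * (length(x2) - 1))
    ci <- unname(quantile(bl, c(alpha, 1 - alpha)))
    data.frame(group1 = g1, group2 = g2, lnvr = est,
               ci_lower = ci[1], ci_upper = ci[2],
               n1 = length(x1), n2 = length(x2), B = B,
               significant = ci[1] > 0 | ci[2] < 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("lnvr_table", "data.frame")
  res
}

#' Fold-change reading of a log variance ratio
#'
#' `exp(|lnVR|)`, the multiplicative factor conventionally quoted when
#' interpreting an lnVR contrast (e.g. `lnVR = 1.38` is read as a roughly
#' 4-fold difference in condition variability).
#'
#' @param lnvr Numeric vector of log variance ratios.
#' @return Numeric vector of fold changes (>= 1).
#' @export
lnvr_fold <- function(lnvr) exp(abs(lnvr))

# shared column validator with informative schema errors
check_fish_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
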