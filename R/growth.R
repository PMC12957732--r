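#' Von Bertalanffy growth prediction
#'
#' `L(t) = Linf * (1 - exp(-K * (t - t0)))`: expected length at age `t`
#' given the asymptotic length `Linf` (mm), growth coefficient `K` (1/yr)
#' and hypothetical age at length zero `t0` (yr). Negative predictions are
#' allowed for `t < t0`; the caller decides how to treat them.
#'
#' @param t Age(s), years.
#' @param linf Asymptotic length, mm (> 0).
#' @param k Growth coefficient, 1/yr (> 0).
#' @param t0 Hypothetical age at length zero, yr.
#' @return Predicted length(s), mm.
#' @examples
#' vbgf_predict(5, linf = 97.86, k = 0.23, t0 = -2)  # ~78.3 mm
#' @export
vbgf_predict <- function(t, linf, k, t0) {
  linf * (1 - exp(-k * (t - t0)))
}

#' Fit the von Bertalanffy growth function by nonlinear least squares
#'
#' Minimises the residual sum of squares of observed lengths around the
#' VBGF curve using Levenberg-Marquardt least squares
#' ([minpack.lm::nlsLM()]). `t0` is either fixed (default -2, matching the
#' common situation where age-zero fish are unobservable and `t0` is
#' pinned) or freely estimated. Start values are analytic (`Linf0` = 1.1 x
#' max observed length; `K0` from a linearised regression of
#' `log(1 - L/Linf0)` on age) with a documented restart ladder over
#' alternative starts if the first attempt fails.
#'
#' @param age Numeric vector of ages (yr).
#' @param length Numeric vector of total lengths (mm), same length.
#' @param t0 Fixed value for `t0` (default -2), or `NULL` to estimate it.
#' @param start Optional named list of start values (`linf`, `k`, and
#'   `t0` when free) overriding the analytic starts.
#' @return Object of class `vbgf_fit`: list with `linf`, `k`, `t0`,
#'   `t0_fixed`, `converged`, `rss`, `n` and the `nls` model.
#' @export
fit_vbgf <- function(age, length, t0 = -2, start = NULL) {
  stopifnot(is.numeric(age), is.numeric(length))
  if (base::length(age) != base::length(length))
    stop("age and length must have equal length", call. = FALSE)
  ok <- complete.cases(age, length)
  age <- age[ok]; length <- length[ok]
  t0_fixed <- !is.null(t0)
  needed <- if (t0_fixed) 3L else 4L
  if (base::length(unique(age)) < needed)
    stop("need at least ", needed, " distinct ages (t0 ",
         if (t0_fixed) "fixed" else "free", ")", call. = FALSE)

  linf0 <- max(length) * 1.1
  frac <- pmin(pmax(1 - length / linf0, 1e-6), 1 - 1e-6)
  k0 <- tryCatch(-unname(coef(lm(log(frac) ~ age))[2]), error = function(e) NA)
  if (!is.finite(k0) || k0 <= 0) k0 <- 0.3

  dat <- data.frame(age = age, len = length)
  starts <- list()
  if (!is.null(start)) starts[[1]] <- start
  for (ksc in c(1, 0.5, 2)) for (lsc in c(1, 1.2)) {
    s <- list(linf = linf0 * lsc, k = k0 * ksc)
    if (!t0_fixed) s$t0 <- 0
    starts[[base::length(starts) + 1L]] <- s
  }
  form <- if (t0_fixed) {
    dat$t0_fix <- t0
    len ~ linf * (1 - exp(-k * (age - t0_fix)))
  } else {
    len ~ linf * (1 - exp(-k * (age - t0)))
  }
  fit <- NULL; errors <- character()
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = s,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { errors <<- c(errors, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("VBGF fit failed after ", base::length(starts), " restarts: ",
         paste(unique(errors), collapse = "; "), call. = FALSE)
  cf <- coef(fit)
  structure(list(linf = unname(cf["linf"]), k = unname(cf["k"]),
                 t0 = if (t0_fixed) t0 else unname(cf["t0"]),
                 t0_fixed = t0_fixed,
                 converged = fit$convInfo$isConv,
                 rss = sum(resid(fit)^2), n = nrow(dat), model = fit),
            class = "vbgf_fit")
}

#' @export
print.vbgf_fit <- function(x, ...) {
  cat("VBGF fit (n = ", x$n, "): Linf = ", signif(x$linf, 6),
      " mm, K = ", signif(x$k, 6), " /yr, t0 = ", signif(x$t0, 4),
      if (x$t0_fixed) " (fixed)" else " (estimated)", "\n", sep = "")
  cat("  residual SS = ", signif(x$rss, 4),
      if (!isTRUE(x$converged)) "  [did not converge]" else "", "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.vbgf_fit <- function(object, ...) {
  c(linf = object$linf, k = object$k, t0 = object$t0)
}

#' Bootstrap VBGF parameters per zone and compare zones by CI overlap
#'
#' Within each group (zone), fish are case-resampled `B` times and the
#' VBGF refitted; percentile 95% CIs are reported per parameter. Two zones
#' are declared to differ for a parameter when their bootstrap CIs are
#' disjoint.
#'
#' @param age,length Numeric vectors of ages and lengths.
#' @param groups Grouping vector (zone), same length.
#' @param B Bootstrap resamples (default 1000; >= 100 recommended for CIs).
#' @param seed Optional integer seed.
#' @param t0 Fixed `t0` (default -2) or `NULL` to estimate per fit.
#' @param conf Confidence level (default 0.95).
#' @param max_fail Maximum tolerated fraction of non-convergent resample
#'   fits per group before aborting (default 0.2).
#' @return Object of class `vbgf_bootstrap`: list with `fits` (per-group
#'   point fits), `ci` (data frame: group, parameter, estimate, boot_mean,
#'   ci_lower, ci_upper), `overlap` (data frame of pairwise verdicts per
#'   parameter: `differs` = CIs disjoint), `B`, `seed`.
#' @export
bootstrap_vbgf <- function(age, length, groups, B = 1000, seed = NULL,
                           t0 = -2, conf = 0.95, max_fail = 0.2) {
  stopifnot(base::length(age) == base::length(length),
            base::length(age) == base::length(groups))
  if (!is.null(seed)) set.seed(seed)
  groups <- as.character(groups)
  levs <- unique(groups)
  alpha <- (1 - conf) / 2
  fits <- list(); ci <- list()
  draws <- list()
  for (g in levs) {
    idx <- which(groups == g)
    fits[[g]] <- fit_vbgf(age[idx], length[idx], t0 = t0)
    n <- base::length(idx)
    boot <- matrix(NA_real_, nrow = B, ncol = 2,
                   dimnames = list(NULL, c("linf", "k")))
    fail <- 0L
    for (b in seq_len(B)) {
      take <- idx[sample.int(n, n, replace = TRUE)]
      fb <- tryCatch(fit_vbgf(age[take], length[take], t0 = t0),
                     error = function(e) NULL)
      if (is.null(fb)) fail <- fail + 1L
      else boot[b, ] <- c(fb$linf, fb$k)
    }
    if (fail > max_fail * B)
      stop("bootstrap unstable in group '", g, "': ", fail, " of ", B,
           " resample fits failed", call. = FALSE)
    draws[[g]] <- boot
    for (p in c("linf", "k")) {
      v <- boot[, p]; v <- v[is.finite(v)]
      ci[[base::length(ci) + 1L]] <- data.frame(
        group = g, parameter = p,
        estimate = if (p == "linf") fits[[g]]$linf else fits[[g]]$k,
        boot_mean = mean(v),
        ci_lower = unname(quantile(v, alpha)),
        ci_upper = unname(quantile(v, 1 - alpha)),
        stringsAsFactors = FALSE)
    }
  }
  ci <- do.call(rbind, ci)
  overlap <- NULL
  if (base::length(levs) >= 2) {
    prs <- combn(levs, 2)
    overlap <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
      do.call(rbind, lapply(c("linf", "k"), function(p) {
        c1 <- ci[ci$group == prs[1, j] & ci$parameter == p, ]
        c2 <- ci[ci$group == prs[2, j] & ci$parameter == p, ]
        data.frame(group1 = prs[1, j], group2 = prs[2, j], parameter = p,
                   differs = c1$ci_lower > c2$ci_upper ||
                             c2$ci_lower > c1$ci_upper,
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  structure(list(fits = fits, ci = ci, overlap = overlap, draws = draws,
                 B = B, seed = seed, t0 = t0),
            class = "vbgf_bootstrap")
}

#' @export
print.vbgf_bootstrap <- function(x, ...) {
  cat("Bootstrapped VBGF parameters (B = ", x$B, ")\n", sep = "")
  print(x$ci, digits = 5)
  if (!is.null(x$overlap)) {
    cat("\nPairwise CI-overlap verdicts:\n")
    print(x$overlap)
  }
  invisible(x)
}
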