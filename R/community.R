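#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum|x - y| / sum(x + y)` over taxa. In `"relative"` mode
#' (the default, appropriate for metabarcoding read tables) each sample is
#' first normalised to proportions, making the matrix invariant to
#' per-sample sequencing depth. `"presence_absence"` binarises first
#' (equivalent to the Sorensen dissimilarity); `"raw"` uses the counts as
#' given.
#'
#' @param x Numeric matrix or data frame, samples x taxa, non-negative.
#' @param mode One of `"relative"`, `"raw"`, `"presence_absence"`.
#' @return A [stats::dist] object with sample labels; entries in \[0, 1\].
#' @export
bray_curtis <- function(x, mode = c("relative", "raw", "presence_absence")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (!is.numeric(x) || any(x < 0))
    stop("abundance table must be numeric and non-negative", call. = FALSE)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  rs <- rowSums(x)
  if (any(rs == 0)) {
    bad <- rownames(x)[rs == 0]
    if (is.null(bad)) bad <- which(rs == 0)
    stop("all-zero sample(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  y <- switch(mode,
              relative = x / rs,
              raw = x,
              presence_absence = (x > 0) * 1)
  vegan::vegdist(y, method = "bray")
}

#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Classical metric scaling: double-centre `-d^2/2`, eigendecompose and
#' return the top-`k` coordinate axes scaled by the square root of their
#' eigenvalues (via [stats::cmdscale()]). Axes with non-positive
#' eigenvalues are dropped; if fewer than `k` positive axes exist the
#' result is flagged `reduced`.
#'
#' @param d A [stats::dist] object or symmetric dissimilarity matrix.
#' @param k Number of axes requested (default 2).
#' @return Object of class `ordination`: list with `points` (n x k'),
#'   `eigenvalues` (all), `method = "PCoA"`, `k`, `reduced`.
#' @export
pcoa_ord <- function(d, k = 2) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (n < k + 1) stop("need at least k + 1 samples", call. = FALSE)
  res <- cmdscale(d, k = min(k, n - 1), eig = TRUE)
  pts <- res$points
  npos <- sum(res$eig > sqrt(.Machine$double.eps) * max(abs(res$eig)))
  reduced <- ncol(pts) < k || npos < k
  if (ncol(pts) > npos) pts <- pts[, seq_len(npos), drop = FALSE]
  colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
  structure(list(points = pts, eigenvalues = res$eig, method = "PCoA",
                 k = k, reduced = reduced),
            class = "ordination")
}

#' Non-metric multidimensional scaling of a dissimilarity matrix
#'
#' Minimises Kruskal's stress-1 over monotone regression and configuration
#' updates, taking the best solution over random starts (plus a metric
#' start), via [vegan::metaMDS()]. Stress is reported on the 0-1
#' proportion scale.
#'
#' @param d A [stats::dist] object or symmetric dissimilarity matrix.
#' @param k Target dimensionality (default 2).
#' @param n_starts Random starts (default 20).
#' @param max_iter Maximum iterations per start (default 300).
#' @param seed Optional integer seed; fixes the random starts.
#' @return Object of class `ordination`: list with `points`, `stress`,
#'   `converged`, `method = "NMDS"`, `k`, `n_starts`.
#' @export
nmds_ord <- function(d, k = 2, n_starts = 20, max_iter = 300, seed = NULL) {
  d <- stats::as.dist(d)
  if (attr(d, "Size") < 4 && k >= 2)
    stop("need at least 4 samples for a 2-D NMDS", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(d, k = k, try = n_starts, trymax = n_starts,
                        maxit = max_iter, trace = 0, autotransform = FALSE,
                        wascores = FALSE)
  conv <- fit$converged
  converged <- isTRUE(conv) || (is.numeric(conv) && conv > 0)
  structure(list(points = fit$points, stress = fit$stress,
                 converged = converged, method = "NMDS", k = k,
                 n_starts = n_starts),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(x$method, " ordination: ", nrow(x$points), " samples, ",
      ncol(x$points), " axes\n", sep = "")
  if (x$method == "NMDS")
    cat("  stress = ", signif(x$stress, 4),
        if (!x$converged) "  [no convergent solution]" else "", "\n",
        sep = "")
  else if (isTRUE(x$reduced))
    cat("  note: fewer positive axes than requested\n")
  invisible(x)
}

# one-way PERMANOVA pseudo-F (Anderson) from a squared-dissimilarity
# matrix and an integer grouping; used for observed and permuted labels
permanova_f <- function(d2, groups_int, n_groups, n) {
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in seq_len(n_groups)) {
    idx <- which(groups_int == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_among <- ss_total - ss_within
  f <- (ss_among / (n_groups - 1)) / (ss_within / (n - n_groups))
  c(f = f, ss_among = ss_among, ss_within = ss_within, ss_total = ss_total)
}

#' Permutational multivariate analysis of variance (one-way)
#'
#' Partitions the squared dissimilarities among and within groups
#' (Anderson's pseudo-F): `SS_total = (1/N) sum_{i<j} d_ij^2`,
#' `SS_within = sum_g (1/n_g) sum_{i<j in g} d_ij^2`,
#' `F = (SS_among/(g-1)) / (SS_within/(N-g))`. The p-value is the
#' permutation estimate `(1 + #[F_perm >= F_obs]) / (1 + n_perm)` under
#' random relabelling of samples (never exactly zero), optionally
#' restricted within strata.
#'
#' @param d A [stats::dist] object or symmetric dissimilarity matrix.
#' @param groups Grouping vector (>= 2 groups, each with >= 2 samples).
#' @param n_perm Number of permutations (default 999; >= 99).
#' @param seed Optional integer seed for the permutations.
#' @param strata Optional blocking vector; permutations shuffle labels
#'   only within blocks.
#' @return Object of class `permanova`: list with `f`, `r_squared`, `p`,
#'   `df` (among, within), `ss` (among, within, total), `n_perm`,
#'   `groups`, `n`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = NULL, strata = NULL) {
  d <- stats::as.dist(d)
  n <- attr(d, "Size")
  if (length(groups) != n)
    stop("groups must match the number of samples", call. = FALSE)
  f <- factor(groups)
  if (nlevels(f) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(f) < 2))
    stop("every group needs at least 2 samples", call. = FALSE)
  if (n_perm < 99) stop("n_perm must be >= 99", call. = FALSE)
  d2 <- as.matrix(d)^2
  gi <- as.integer(f)
  ng <- nlevels(f)
  obs <- permanova_f(d2, gi, ng, n)
  if (!is.null(seed)) set.seed(seed)
  permute_idx <- if (is.null(strata)) {
    function() sample.int(n)
  } else {
    blocks <- split(seq_len(n), strata)
    function() {
      idx <- seq_len(n)
      for (b in blocks) idx[b] <- b[sample.int(length(b))]
      idx
    }
  }
  count <- 0L
  for (b in seq_len(n_perm)) {
    fp <- permanova_f(d2, gi[permute_idx()], ng, n)
    if (fp[["f"]] >= obs[["f"]]) count <- count + 1L
  }
  structure(list(f = obs[["f"]],
                 r_squared = obs[["ss_among"]] / obs[["ss_total"]],
                 p = (1 + count) / (1 + n_perm),
                 df = c(among = ng - 1L, within = n - ng),
                 ss = c(among = obs[["ss_among"]],
                        within = obs[["ss_within"]],
                        total = obs[["ss_total"]]),
                 n_perm = n_perm, groups = levels(f), n = n),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (", x$n, " samples, ", length(x$groups), " groups, ",
      x$n_perm, " permutations)\n", sep = "")
  cat("  pseudo-F = ", signif(x$f, 5), ", R2 = ", signif(x$r_squared, 4),
      ", p = ", signif(x$p, 4), "\n", sep = "")
  invisible(x)
}

#' Pairwise PERMANOVA with Bonferroni correction
#'
#' Runs [permanova()] on the sub-matrix of every pair of groups and
#' applies a Bonferroni correction `p_adj = min(1, p * C(g, 2))`.
#'
#' @inheritParams permanova
#' @return Data frame (class `pairwise_permanova`): `group1`, `group2`,
#'   `f`, `r_squared`, `p`, `p_adjusted`.
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(d)
  f <- factor(groups)
  levs <- levels(f)
  if (length(levs) < 2) stop("need at least 2 groups", call. = FALSE)
  m <- as.matrix(d)
  prs <- combn(levs, 2)
  n_comp <- ncol(prs)
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(n_comp), function(j) {
    idx <- which(f %in% prs[, j])
    sub <- stats::as.dist(m[idx, idx])
    res <- permanova(sub, droplevels(f[idx]), n_perm = n_perm)
    data.frame(group1 = prs[1, j], group2 = prs[2, j], f = res$f,
               r_squared = res$r_squared, p = res$p,
               p_adjusted = min(1, res$p * n_comp),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("pairwise_permanova", "data.frame")
  res
}
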