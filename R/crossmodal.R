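#' Spearman rank correlation with Gaussian-approximation p and Fisher-z CI
#'
#' Average ranks for ties; missing pairs dropped pairwise.  The two-tailed
#' p-value uses the Gaussian approximation `z = rho * sqrt(n - 1)`; the 95%
#' CI transforms rho to Fisher z with variance `1 / (n - 3)`.  For small
#' samples an exact permutation p-value (all n! rank permutations) is
#' available.
#'
#' @param x,y equal-length numeric vectors.
#' @param exact if `TRUE` and `n <= 8`, compute the permutation p-value by
#'   full enumeration instead of the Gaussian approximation.
#' @return list of class `"correlation_result"`: `rho`, `n_pairs`, `p`,
#'   `ci95` (length 2), `method`.
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(structure(list(rho = if (n >= 2) stats::cor(rank(x), rank(y)) else NA_real_,
                          n_pairs = n, p = NA_real_,
                          ci95 = c(NA_real_, NA_real_),
                          method = "undefined (n < 3)"),
                     class = "correlation_result"))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (exact && n <= 8L) {
    rx <- rank(x)
    perms <- permutations_of(n)
    ry <- rank(y)
    rhos <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    z <- rho * sqrt(n - 1)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Gaussian approximation"
  }
  ci <- if (n > 3 && abs(rho) < 1) {
    zr <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    tanh(zr + c(-1, 1) * stats::qnorm(0.975) * se)
  } else c(NA_real_, NA_real_)
  structure(list(rho = rho, n_pairs = n, p = p, ci95 = ci, method = method),
            class = "correlation_result")
}

# all permutations of 1..n (n small), rows = permutations
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                 sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(blk)
    r <- r + nrow(sub)
  }
  out
}

#' Pairwise Spearman correlation matrix of odor activity maps
#'
#' Maps are compared over matched locations (grid cells or angular bins),
#' pairwise-complete.
#'
#' @param maps named list of equal-shape numeric vectors/matrices (one per
#'   odorant); `NA` cells are dropped pairwise.
#' @return symmetric correlation matrix with unit diagonal and odorant
#'   dimnames.
#' @export
odor_map_correlation <- function(maps) {
  n <- length(maps)
  labs <- names(maps) %||% as.character(seq_len(n))
  vecs <- lapply(maps, function(m) {
    if (inherits(m, "angular_profile")) m$values else as.numeric(m)
  })
  len <- unique(vapply(vecs, length, integer(1)))
  if (length(len) != 1L) stop("maps must share a common shape")
  m <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i) {
      r <- spearman_cor(vecs[[i]], vecs[[j]])$rho
      m[i, j] <- r
      m[j, i] <- r
    }
  }
  dimnames(m) <- list(labs, labs)
  m
}

#' Cluster odorants from their map-correlation matrix
#'
#' Average-linkage hierarchical clustering on distance `1 - rho`, cut at
#' `k` groups.  Cluster labels are renumbered so cluster 1 contains the
#' first odorant.
#'
#' @param mat symmetric correlation matrix ([odor_map_correlation()]).
#' @param k number of groups (default 2).
#' @return named integer vector of cluster assignments, with the `hclust`
#'   tree in attribute `"tree"`.
#' @export
cluster_odorants <- function(mat, k = 2L) {
  stopifnot(isSymmetric(unname(mat)))
  tree <- stats::hclust(stats::as.dist(1 - mat), method = "average")
  cl <- stats::cutree(tree, k = k)
  # stable numbering: first appearance order
  uu <- unique(cl)
  cl <- stats::setNames(match(cl, uu), names(cl))
  structure(cl, tree = tree)
}

#' Angle-matched correlation of histology and calcium profiles
#'
#' Pairs the two angular profiles bin by bin over the dorsoventral domain
#' (bins must match exactly), computes the Spearman correlation, and fits
#' an ordinary least-squares regression of the calcium values on the
#' histology values with a pointwise 95% confidence band.
#'
#' @param hist_profile,calcium_profile `"angular_profile"` objects on
#'   identical bin edges.
#' @param exact passed to [spearman_cor()].
#' @return list: `cor` (`"correlation_result"`), `n_pairs`, `slope`,
#'   `intercept`, `slope_ci95`, `band` (data frame `x`, `fit`, `lwr`,
#'   `upr`).
#' @export
angle_matched_correlation <- function(hist_profile, calcium_profile,
                                      exact = FALSE) {
  stopifnot(inherits(hist_profile, "angular_profile"),
            inherits(calcium_profile, "angular_profile"))
  if (!isTRUE(all.equal(hist_profile$bin_edges, calcium_profile$bin_edges))) {
    stop("profiles must share identical bin edges")
  }
  x <- hist_profile$values
  y <- calcium_profile$values
  ok <- !is.na(x) & !is.na(y)
  cr <- spearman_cor(x[ok], y[ok], exact = exact)
  fit <- stats::lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  ci <- stats::confint(fit, "x", level = 0.95)
  band <- cbind(x = x[ok],
                as.data.frame(stats::predict(fit, interval = "confidence",
                                             level = 0.95)))
  list(cor = cr, n_pairs = cr$n_pairs,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_ci95 = as.numeric(ci),
       band = band)
}

#' Student's unpaired two-sample t test
#'
#' Equal-variance two-tailed t test; `df = n1 + n2 - 2`.
#'
#' @param group_a,group_b numeric samples.
#' @return list of class `"stat_result"`: `statistic`, `df`, `p`, `test`,
#'   `adjustment`.
#' @export
unpaired_t <- function(group_a, group_b) {
  ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
  structure(list(statistic = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, test = "Student unpaired t (two-tailed)",
                 adjustment = "none"),
            class = "stat_result")
}

#' Two-way ANOVA with Bonferroni-adjusted genotype contrasts
#'
#' Two-factor (genotype x region) ANOVA with interaction on a marker count
#' table, followed by per-region Student t contrasts between genotypes
#' with Bonferroni adjustment (`p_adj = min(1, m * p)`, m = number of
#' region levels).
#'
#' @param counts data frame with `genotype`, `region`, `value` (one
#'   marker).
#' @return list: `anova` (data frame term / df / F / p), `posthoc`
#'   (data frame region / t / df / p_raw / p_bonferroni).
#' @export
two_way_anova_bonferroni <- function(counts) {
  d <- data.frame(genotype = factor(counts$genotype),
                  region = factor(counts$region),
                  value = counts$value)
  fit <- stats::aov(value ~ genotype * region, data = d)
  s <- summary(fit)[[1]]
  terms <- trimws(rownames(s))
  anova_tab <- data.frame(term = terms, df = s$Df, ss = s$`Sum Sq`,
                          F = s$`F value`,
                          p = s$`Pr(>F)`)[terms != "Residuals", ]
  rownames(anova_tab) <- NULL
  m <- nlevels(d$region)
  ph <- lapply(levels(d$region), function(r) {
    dd <- d[d$region == r, ]
    g <- levels(d$genotype)
    tt <- tryCatch(
      unpaired_t(dd$value[dd$genotype == g[1]],
                 dd$value[dd$genotype == g[2]]),
      error = function(e) list(statistic = NA_real_, df = NA_real_,
                               p = NA_real_))
    data.frame(region = r, t = tt$statistic, df = tt$df, p_raw = tt$p,
               p_bonferroni = min(1, m * tt$p))
  })
  list(anova = anova_tab, posthoc = do.call(rbind, ph))
}
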