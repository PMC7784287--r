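test_that("spearman handles monotone transforms, reversals and ties", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  set.seed(40)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(log(a - min(a) + 1), b)$rho)

  # exhaustive average-rank oracle with ties
  tied_x <- c(2, 2, 5, 7, 7, 7, 1, 9)
  tied_y <- c(1, 4, 4, 2, 8, 8, 3, 5)
  rank_oracle <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      less + (eq + 1) / 2
    }, numeric(1))
  }
  rx <- rank_oracle(tied_x); ry <- rank_oracle(tied_y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearman_cor(tied_x, tied_y)$rho, num / den)
  # and cross-checked against the reference implementation
  expect_equal(spearman_cor(tied_x, tied_y)$rho,
               unname(cor.test(tied_x, tied_y, method = "spearman",
                               exact = FALSE)$estimate))
})

test_that("spearman p-values and CIs follow the stated approximations", {
  set.seed(41)
  x <- rnorm(50); y <- x + rnorm(50)
  r <- spearman_cor(x, y)
  z <- r$rho * sqrt(r$n_pairs - 1)
  expect_equal(r$p, 2 * pnorm(-abs(z)))
  se <- 1 / sqrt(r$n_pairs - 3)
  expect_equal(r$ci95, tanh(atanh(r$rho) + c(-1, 1) * qnorm(0.975) * se))
  expect_identical(r$method, "Gaussian approximation")
  expect_true(r$ci95[1] < r$rho && r$rho < r$ci95[2])

  # missing pairs dropped pairwise
  xm <- c(x, NA); ym <- c(y, 1)
  expect_identical(spearman_cor(xm, ym)$n_pairs, 50L)

  # exact permutation p at small n agrees with cor.test's exact p
  xs <- c(3, 1, 4, 1.5, 9, 2.6)
  ys <- c(2, 7, 1, 8, 2.8, 1.9)
  pe <- spearman_cor(xs, ys, exact = TRUE)
  expect_identical(pe$method, "exact permutation")
  expect_equal(pe$p, cor.test(xs, ys, method = "spearman", exact = TRUE)$p.value)
})

test_that("odor map correlation matrices are symmetric with unit diagonal", {
  set.seed(42)
  maps <- list(L = rnorm(60), A = rnorm(60), H = rnorm(60))
  m <- odor_map_correlation(maps)
  expect_equal(diag(m), c(L = 1, A = 1, H = 1))
  expect_lt(max(abs(m - t(m))), 1e-12)

  # two maps with disjoint foci anticorrelate
  f1 <- c(rep(1, 20), rep(0, 40)) + runif(60, 0, 0.01)
  f2 <- c(rep(0, 40), rep(1, 20)) + runif(60, 0, 0.01)
  m2 <- odor_map_correlation(list(a = f1, b = f2))
  expect_lt(m2["a", "b"], 0)
  expect_error(odor_map_correlation(list(a = 1:5, b = 1:6)), "shape")
})

test_that("clustering recovers planted blocks, matching a partition oracle", {
  labs <- c("L", "A", "E", "G", "AP", "HA", "H")
  m <- matrix(-0.3, 7, 7, dimnames = list(labs, labs))
  m[1:3, 1:3] <- 0.8
  m[4:7, 4:7] <- 0.8
  diag(m) <- 1
  cl <- cluster_odorants(m, k = 2)
  expect_equal(unname(cl), c(1, 1, 1, 2, 2, 2, 2), ignore_attr = TRUE)

  # oracle: enumerate all 2-partitions, pick max(within - between rho)
  best <- NULL; best_score <- -Inf
  for (mask in 1:62) {
    sel <- as.logical(bitwAnd(mask, 2^(0:6)) > 0)
    if (!any(sel) || all(sel)) next
    within <- c(m[sel, sel][upper.tri(m[sel, sel])],
                m[!sel, !sel][upper.tri(m[!sel, !sel])])
    between <- m[sel, !sel]
    score <- mean(within) - mean(between)
    if (is.nan(score)) score <- -mean(between)
    if (score > best_score) { best_score <- score; best <- sel }
  }
  expect_true(identical(which(best), 1:3) || identical(which(!best), 1:3))

  expect_equal(unname(cluster_odorants(m, k = 1)), rep(1, 7),
               ignore_attr = TRUE)
})

test_that("angle-matched correlation pairs bins and fits the regression", {
  v <- seq(0.5, 179.5)
  p1 <- build_profile(v, v / 100, plane = "sagittal")
  p2 <- build_profile(v, v / 100, plane = "sagittal")
  am <- suppressWarnings(angle_matched_correlation(p1, p2))  # exact fit
  expect_identical(am$n_pairs, 180L)
  expect_equal(am$cor$rho, 1)
  expect_equal(am$slope, 1)
  expect_equal(am$intercept, 0, tolerance = 1e-9)
  expect_true(all(am$band$lwr <= am$band$fit & am$band$fit <= am$band$upr))

  p3 <- build_profile(v, rep(1, 180), plane = "sagittal", bin_deg = 5)
  expect_error(angle_matched_correlation(p1, p3), "bin edges")

  # missing bins are dropped pairwise, n_pairs reported
  vals <- v / 100; vals[c(5, 9)] <- NA
  p4 <- build_profile(v, vals, plane = "sagittal")
  expect_identical(suppressWarnings(angle_matched_correlation(p4, p2))$n_pairs,
                   178L)
})

test_that("Student t reports df = n1 + n2 - 2 and matches the closed form", {
  a <- c(5.1, 4.9, 6.2, 5.5, 5.0, 5.9)
  b <- c(4.2, 4.8, 4.1, 5.1, 4.4, 4.0)
  tt <- unpaired_t(a, b)
  expect_equal(tt$df, 10)
  sp2 <- ((5) * var(a) + (5) * var(b)) / 10
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 6 + 1 / 6))
  expect_equal(tt$statistic, t_oracle)
  expect_equal(tt$p, 2 * pt(-abs(t_oracle), 10))

  same <- unpaired_t(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
})

test_that("two-way ANOVA matches hand-computed sums of squares", {
  # 2x2 balanced design, n = 3 per cell
  d <- data.frame(
    genotype = rep(c("WT", "TG"), each = 6),
    region = rep(rep(c("endo", "ecto"), each = 3), 2),
    value = c(10, 11, 9, 14, 15, 13, 9, 10, 11, 20, 22, 21))
  res <- two_way_anova_bonferroni(d)

  grand <- mean(d$value)
  cell <- with(d, tapply(value, list(genotype, region), mean))
  gm <- rowMeans(cell); rm_ <- colMeans(cell)
  n <- 3; a <- 2; b <- 2
  ss_g <- n * b * sum((gm - grand)^2)
  ss_r <- n * a * sum((rm_ - grand)^2)
  ss_gr <- n * sum((sweep(sweep(cell, 1, gm), 2, rm_) + grand)^2)
  ss_e <- sum((d$value - cell[cbind(d$genotype, d$region)])^2)
  f_g <- (ss_g / 1) / (ss_e / 8)
  f_r <- (ss_r / 1) / (ss_e / 8)
  f_gr <- (ss_gr / 1) / (ss_e / 8)

  tab <- res$anova
  expect_equal(tab$F[tab$term == "genotype"], f_g)
  expect_equal(tab$F[tab$term == "region"], f_r)
  expect_equal(tab$F[tab$term == "genotype:region"], f_gr)

  # Bonferroni: adjusted p = min(1, m * p_raw), m = 2 regions
  expect_equal(res$posthoc$p_bonferroni,
               pmin(1, 2 * res$posthoc$p_raw))

  # all-equal cells: no effect sums of squares (to numerical precision)
  d0 <- d; d0$value <- 5
  res0 <- two_way_anova_bonferroni(d0)
  expect_lt(max(res0$anova$ss), 1e-20)
  expect_true(all(is.na(res0$posthoc$t)))
})
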