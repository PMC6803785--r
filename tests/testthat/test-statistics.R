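# Lesion volumes (mm^3) measured for the four treated animals: serial
# histology vs the MDWI core segmentation, and body weights (kg).
histology_volumes <- c(315, 418, 297, 351)
mdwi_volumes <- c(302, 432, 337, 319)
pig_weights <- c(5.0, 6.7, 5.3, 6.3)

test_that("roi_mean averages valid masked voxels", {
  m <- array(5, c(4, 4, 4))
  msk <- array(FALSE, c(4, 4, 4)); msk[1:2, 1, 1] <- TRUE
  expect_identical(roi_mean(m, msk), 5)
  m[1, 1, 1] <- 2; m[2, 1, 1] <- 4
  expect_identical(roi_mean(m, msk), 3)
  m[1, 1, 1] <- NA
  expect_identical(roi_mean(m, msk), 4)      # NA voxels are excluded
  expect_error(roi_mean(m, array(FALSE, c(4, 4, 4))), "empty ROI")
  expect_error(roi_mean(m, array(TRUE, c(3, 3, 3))), "geometry")
})

test_that("reference FA of the noiseless phantom matches the closed form", {
  ph <- make_phantom(small_spec(seed = 44, noise_sigma = 0))
  fa <- eigen_metrics(fit_tensor_loglinear(ph$pre, ph$truth$reference))$FA
  expect_equal(roi_mean(fa, ph$truth$reference), 0.799023, tolerance = 1e-6)
})

test_that("reference normalization is a plain percentage", {
  expect_identical(normalize_to_reference(0.5, 1), 50)
  expect_identical(normalize_to_reference(4.2, 4.2), 100)
  expect_identical(normalize_to_reference(0.75, 0.5), 150)
  expect_error(normalize_to_reference(1, 0), "reference")
})

test_that("paired t on the histology/MDWI volume pairs matches a numeric oracle", {
  res <- paired_t_test(histology_volumes, mdwi_volumes)
  # oracle: closed-form statistic + numerically integrated t tail
  d <- histology_volumes - mdwi_volumes
  t_oracle <- mean(d) / (sd(d) / sqrt(length(d)))
  p_oracle <- 2 * stats::integrate(function(x) stats::dt(x, df = 3),
                                   abs(t_oracle), Inf)$value
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p_raw, p_oracle, tolerance = 1e-6)
  expect_identical(res$df, 3)
  expect_equal(abs(res$statistic), 0.143, tolerance = 5e-4)
  expect_equal(res$p_raw, 0.895, tolerance = 5e-3)
  expect_gt(res$p_raw, 0.05)    # volumes are statistically comparable
})

test_that("paired t degenerate contracts", {
  x <- c(1, 2, 3, 4)
  res <- paired_t_test(x, x)
  expect_identical(res$statistic, 0)
  expect_identical(res$p_raw, 1)
  expect_error(paired_t_test(x + 1, x), "degenerate")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
  expect_error(paired_t_test(1, 2), "at least two")
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_identical(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
  p <- withr::with_seed(3, runif(20)^2)
  adj <- fdr_adjust(p)
  expect_true(all(adj >= p))
  perm <- sample(20)
  expect_equal(fdr_adjust(p[perm]), adj[perm])   # permutation equivariance
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  groups <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5))
  res <- oneway_anova(groups)
  # oracle: SSB = 3*((2-3)^2 + 0 + (4-3)^2) = 6 over df 2;
  #         SSW = 2 + 2 + 2 = 6 over df 6 -> F = 3/1
  expect_equal(res$statistic, 3, tolerance = 1e-12)
  expect_identical(res$df, "2,6")
  same <- list(a = c(1, 2), b = c(1, 2))
  res0 <- oneway_anova(same)
  expect_identical(res0$statistic, 0)
  expect_identical(res0$p_raw, 1)
  expect_error(oneway_anova(list(a = 1, b = c(1, 2))), "at least two")
})

test_that("two-group ANOVA F equals the squared pooled t statistic", {
  withr::with_seed(7, {
    for (i in 1:5) {
      x <- rnorm(6); y <- rnorm(8, mean = 0.5)
      Fv <- oneway_anova(list(x = x, y = y))$statistic
      tv <- stats::t.test(x, y, var.equal = TRUE)$statistic
      expect_equal(Fv, unname(tv)^2, tolerance = 1e-9)
    }
  })
})

test_that("Tukey HSD flags the separated pair and matches a ptukey oracle", {
  groups <- list(g1 = c(0, 0, 0, 0), g2 = c(10, 10, 10, 10.001),
                 g3 = c(0.001, 0, 0, 0))
  tk <- tukey_hsd(groups)
  expect_identical(nrow(tk), 3L)                 # k(k-1)/2 pairs
  p12 <- tk$p_adj[tk$comparison == "g2-g1"]
  p13 <- tk$p_adj[tk$comparison == "g3-g1"]
  expect_lt(p12, 0.05)
  expect_gt(p13, 0.05)
  # oracle: studentized range q = |diff| / sqrt(MSE / n)
  df_frame <- data.frame(v = unlist(groups),
                         g = rep(names(groups), each = 4))
  mse <- sum(unlist(lapply(groups, function(g) sum((g - mean(g))^2)))) / 9
  q12 <- abs(mean(groups$g2) - mean(groups$g1)) / sqrt(mse / 4)
  expect_equal(p12, stats::ptukey(q12, 3, 9, lower.tail = FALSE),
               tolerance = 1e-6)

  same <- list(a = c(2, 2), b = c(2, 2))
  expect_true(all(tukey_hsd(same)$p_adj == 1))
})

test_that("layer report detects the graded lesion effect", {
  ph <- make_phantom(small_spec(seed = 55))
  layers <- make_layers(ph$truth$lesion)
  roi <- layers$nested_outer | ph$truth$reference
  pre <- compute_scalar_maps(ph$pre, roi)$maps
  post <- compute_scalar_maps(ph$post, roi)$maps
  rep1 <- build_layer_report(pre, post, layers, ph$truth$reference)

  tab <- rep1$table
  expect_identical(nrow(tab), 30L)    # 2 timepoints x 3 layers x 5 metrics
  for (m in c("ADC", "AD", "RD", "MD", "FA")) {
    core_pre <- tab$raw_mean[tab$timepoint == "pre" & tab$layer == "core" &
                             tab$metric == m]
    core_post <- tab$raw_mean[tab$timepoint == "post" & tab$layer == "core" &
                              tab$metric == m]
    expect_lt(core_post, core_pre)    # every metric drops in the core
  }
  dmd <- sapply(c("core", "boundary", "outer"), function(ly) {
    abs(tab$raw_mean[tab$timepoint == "post" & tab$layer == ly &
                     tab$metric == "MD"] -
        tab$raw_mean[tab$timepoint == "pre" & tab$layer == ly &
                     tab$metric == "MD"])
  })
  expect_true(dmd["core"] >= dmd["boundary"] &&
              dmd["boundary"] >= dmd["outer"])   # radially graded effect
  expect_identical(nrow(rep1$paired), 15L)
  expect_true(all(rep1$paired$p_adj >= rep1$paired$p_raw))
})

test_that("null phantom yields an unchanged report with no significant cells", {
  ph <- make_phantom(small_spec(seed = 56, lesion_core_scale = 1,
                                noise_sigma = 0))
  layers <- make_layers(ph$truth$lesion)
  roi <- layers$nested_outer | ph$truth$reference
  maps_pre <- compute_scalar_maps(ph$pre, roi)$maps
  maps_post <- compute_scalar_maps(ph$post, roi)$maps
  rep0 <- build_layer_report(maps_pre, maps_post, layers, ph$truth$reference)
  pre_rows <- rep0$table[rep0$table$timepoint == "pre", -1]
  post_rows <- rep0$table[rep0$table$timepoint == "post", -1]
  rownames(pre_rows) <- rownames(post_rows) <- NULL
  expect_equal(pre_rows, post_rows, tolerance = 1e-12)
  expect_false(any(rep0$paired$significant))
  expect_true(all(rep0$paired$p_raw == 1))
})

test_that("null phantoms with noise keep the FDR-significant fraction nominal", {
  nsig <- 0L; ntot <- 0L
  for (r in 1:40) {
    ph <- make_phantom(small_spec(seed = 3000 + r, lesion_core_scale = 1))
    layers <- make_layers(ph$truth$lesion)
    roi <- layers$nested_outer | ph$truth$reference
    pre <- compute_scalar_maps(ph$pre, roi)$maps
    post <- compute_scalar_maps(ph$post, roi)$maps
    rep0 <- build_layer_report(pre, post, layers, ph$truth$reference)
    nsig <- nsig + sum(rep0$paired$significant)
    ntot <- ntot + nrow(rep0$paired)
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / ntot)
  expect_lte(nsig / ntot, bound)
})
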