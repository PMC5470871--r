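test_that("repeated-measures ANOVA matches the aov error-stratum oracle", {
  set.seed(77)
  ct <- condition_table()
  for (n in c(3, 4, 6)) {
    tab <- random_amp_table(n, rnorm(6))
    got <- rm_anova_2x3(tab)
    # independent oracle: base-R aov with subject error strata
    cells <- merge(tab, ct[, c("condition", "stimulus", "cue")])
    cells$subject <- factor(cells$subject)
    cells$stimulus <- factor(cells$stimulus)
    cells$cue <- factor(cells$cue)
    fit <- stats::aov(amplitude ~ stimulus * cue +
                        Error(subject / (stimulus * cue)), data = cells)
    sm <- summary(fit)
    f_or <- c(sm[["Error: subject:stimulus"]][[1]][1, "F value"],
              sm[["Error: subject:cue"]][[1]][1, "F value"],
              sm[["Error: subject:stimulus:cue"]][[1]][1, "F value"])
    expect_equal(got$F, unname(f_or), tolerance = 1e-10)
    expect_equal(got$df2, c(n - 1L, 2L * (n - 1L), 2L * (n - 1L)))
  }
})

test_that("ANOVA flags degenerate tables and handles incomplete subjects", {
  tab <- amp_table(matrix(5, 4, 6))
  out <- rm_anova_2x3(tab)
  expect_true(all(out$degenerate))
  expect_true(all(is.na(out$F)))
  set.seed(1)
  tab2 <- random_amp_table(3, rnorm(6))
  expect_warning(out2 <- rm_anova_2x3(tab2[-1, ]), "incomplete")
  expect_equal(attr(out2, "n_subjects"), 2L)
  expect_error(suppressWarnings(rm_anova_2x3(tab2[1:6, ][-1, ])), "subjects")
})

test_that("paired t matches the closed form, with edge cases flagged", {
  a <- c(1.2, 2.4, 0.8, 3.1); b <- c(0.9, 2.9, 0.3, 2.2)
  got <- paired_t(a, b)
  d <- a - b
  t_or <- mean(d) / (sd(d) / sqrt(4))
  expect_equal(got$t, t_or, tolerance = 1e-12)
  expect_equal(got$df, 3)
  expect_equal(got$p, 2 * pt(-abs(t_or), 3), tolerance = 1e-12)
  # sign flip negates t
  expect_equal(paired_t(b, a)$t, -t_or, tolerance = 1e-12)
  # identical inputs: t = 0, p = 1, zero-variance flag
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_true(same$zero_variance)
})

test_that("BH rejections equal the brute-force step-up rule", {
  expect_identical(fdr_bh(numeric(0)), logical(0))
  expect_false(any(fdr_bh(rep(1, 10))))
  expect_true(fdr_bh(0.01))
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  # brute-force enumeration: largest k with p_(k) <= k q / m
  m <- length(p); o <- order(p)
  k <- max(c(0, which(p[o] <= seq_len(m) * 0.05 / m)))
  want <- rep(FALSE, m); if (k > 0) want[o[seq_len(k)]] <- TRUE
  expect_identical(fdr_bh(p), want)
})

test_that("the comparison report calls the generating model", {
  sim_pc <- simulate_condition_amplitudes(
    generative_spec("pc-pain", c(1, 2), n_subjects = 28, snr = "high",
                    seed = 21))
  rep_pc <- compare_all_models(sim_pc$amplitudes)
  expect_gt(pair_logbf(rep_pc, "pc-pain", "intensity"), 3)
  # intensity-generated data: the comparison flips
  sim_int <- simulate_condition_amplitudes(
    generative_spec("intensity", 1, n_subjects = 28, snr = "high",
                    seed = 22))
  rep_int <- compare_all_models(sim_int$amplitudes)
  expect_lt(pair_logbf(rep_int, "pc-pain", "intensity"), -3)
  # span-identical pair reported as exactly tied
  row3 <- rep_int$pairs[rep_int$pairs$model_a == "additive" &
                          rep_int$pairs$model_b == "pc-signed", ]
  expect_equal(row3$log_bf, 0, tolerance = 1e-10)
  expect_equal(row3$call, "none")
})

test_that("model recovery is seed-reproducible and sharp at high SNR", {
  specs <- list(
    "intensity" = generative_spec("intensity", 1, n_subjects = 12,
                                  snr = "high"),
    "pc-pain" = generative_spec("pc-pain", c(1, 2), n_subjects = 12,
                                snr = "high"))
  c1 <- model_recovery(specs, replicates = 5, seed = 8)
  c2 <- model_recovery(specs, replicates = 5, seed = 8)
  expect_identical(c1, c2)
  diag5 <- attr(c1, "class_diagonal")
  expect_true(all(diag5 >= 0.8))
  expect_equal(rowSums(c1), c("intensity" = 1, "pc-pain" = 1))
})

test_that("voxel-wise log-BF maps recover the generating side of the blend", {
  spec_pc <- generative_spec("pc-pain", c(1, 2), n_subjects = 10, snr = "high")
  spec_int <- generative_spec("intensity", 1, n_subjects = 10, snr = "high")
  grid <- simulate_voxel_grid(shape = c(4L, 5L, 3L),
                              lambda_fun = function(y) rep(1, length(y)),
                              spec_pc = spec_pc, spec_int = spec_int,
                              mask = array(TRUE, c(4, 5, 3)), seed = 17)
  maps <- voxelwise_logbf(grid)
  in_post <- maps$log_bf[maps$premask]
  expect_gt(length(in_post), 0)
  expect_gte(mean(in_post > 0), 0.95)
  # a single-voxel mask equals the scalar model comparison
  mask1 <- array(FALSE, c(4, 5, 3)); mask1[2, 3, 2] <- TRUE
  grid1 <- grid; grid1$mask <- mask1
  maps1 <- voxelwise_logbf(grid1, premask_p = 1)
  conds <- condition_table()$condition
  Y <- t(grid$data[2, 3, 2, , ])
  tab <- data.frame(subject = rep(1:10, each = 6),
                    condition = rep(conds, 10),
                    amplitude = as.vector(t(Y)))
  expect_equal(maps1$log_bf[2, 3, 2],
               log_bf_compare(tab, "pc-pain", "intensity"), tolerance = 1e-10)
})

test_that("noise-only grids leave the thresholded map essentially empty", {
  spec0 <- generative_spec("intensity", 0, n_subjects = 10,
                           sd_subject = 0.2, sd_noise = 0.3)
  grid <- simulate_voxel_grid(shape = c(4L, 5L, 3L),
                              lambda_fun = function(y) rep(1, length(y)),
                              spec_pc = spec0,
                              spec_int = generative_spec("intensity", 0,
                                                         n_subjects = 10,
                                                         sd_subject = 0.2,
                                                         sd_noise = 0.3),
                              mask = array(TRUE, c(4, 5, 3)), seed = 31)
  maps <- suppressWarnings(voxelwise_logbf(grid))
  # the p < 0.005 omnibus pre-mask screens out almost everything
  expect_lte(sum(maps$premask), 3)
  expect_lte(sum(!is.na(maps$thresholded)), 3)
})

test_that("gradient profiles are flat for constant maps and split hemispheres", {
  coords <- list(x = c(-3, -1, 1, 3), y = c(-4, 0, 4), z = c(-1, 1))
  m <- array(2.5, dim = c(4, 3, 2))
  prof <- gradient_profile(m, coords)
  expect_true(all(prof$mean_log_bf == 2.5))
  expect_equal(sort(unique(prof$hemisphere)), c("left", "right"))
  # an all-NA map yields an all-missing profile
  prof_na <- gradient_profile(array(NA_real_, c(4, 3, 2)), coords)
  expect_true(all(is.na(prof_na$mean_log_bf)))
  expect_true(all(prof_na$n_voxels == 0))
})

test_that("pattern expression is the masked dot product per condition", {
  spec_pc <- generative_spec("pc-pain", c(1, 2), n_subjects = 3,
                             sd_subject = 0, sd_noise = 0)
  spec_int <- generative_spec("intensity", 1, n_subjects = 3,
                              sd_subject = 0, sd_noise = 0)
  grid <- simulate_voxel_grid(shape = c(3L, 4L, 3L),
                              lambda_fun = function(y) rep(0, length(y)),
                              spec_pc = spec_pc, spec_int = spec_int,
                              mask = array(TRUE, c(3, 4, 3)), seed = 5)
  # zero weight map: all-zero expression
  w0 <- array(0, c(3, 4, 3))
  expect_true(all(pattern_expression(w0, grid)$amplitude == 0))
  # single-voxel unit weight returns that voxel's condition values
  w1 <- array(0, c(3, 4, 3)); w1[2, 2, 2] <- 1
  expr1 <- pattern_expression(w1, grid)
  expect_equal(expr1$amplitude[expr1$subject == 1],
               unname(grid$data[2, 2, 2, , 1]), tolerance = 1e-12)
  expect_error(pattern_expression(array(0, c(2, 2, 2)), grid), "shape")
})

test_that("intensity-template expression shows a stimulus effect, no interaction", {
  spec_int <- generative_spec("intensity", 1, n_subjects = 12,
                              sd_subject = 0.3, sd_noise = 0.15)
  grid <- simulate_voxel_grid(shape = c(4L, 4L, 3L),
                              lambda_fun = function(y) rep(0, length(y)),
                              spec_pc = generative_spec("pc-pain", c(1, 2),
                                                        n_subjects = 12),
                              spec_int = spec_int,
                              mask = array(TRUE, c(4, 4, 3)), seed = 13)
  w <- array(1 / 48, c(4, 4, 3))
  expr <- pattern_expression(w, grid)
  an <- rm_anova_2x3(expr)
  expect_lt(an$p[an$effect == "stimulus"], 0.001)
  expect_gt(an$p[an$effect == "cue_by_stimulus"], 0.01)
})
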