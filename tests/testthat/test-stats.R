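test_that("mixed RM-ANOVA matches the projection oracle on a fixed design", {
  # 2 groups x 3 subjects x 3 times, small integer table
  d <- expand.grid(s = 1:6, t = 1:3)
  d$g <- ifelse(d$s <= 3, "A", "B")
  d$y <- c(10, 9, 11, 7, 6, 8,
           9, 8, 10, 5, 5, 6,
           8, 8, 9, 4, 3, 5)
  at <- rm_anova_mixed(d, value = "y", group = "g", subject = "s",
                       time = "t")
  orc <- rm_anova_glm_oracle(d)
  expect_equal(at$F[at$effect == "group"], orc$F_group, tolerance = 1e-8)
  expect_equal(at$F[at$effect == "time"], orc$F_time, tolerance = 1e-8)
  expect_equal(at$F[at$effect == "group:time"], orc$F_inter,
               tolerance = 1e-8)
  expect_equal(at$SS, unname(orc$SS), tolerance = 1e-8)
  # total SS decomposes
  expect_equal(sum(at$SS), sum((d$y - mean(d$y))^2), tolerance = 1e-8)
  # agreement with the aov error-strata route as a second oracle
  s <- summary(stats::aov(y ~ g * factor(t) + Error(factor(s)), data = d))
  expect_equal(at$F[at$effect == "group"],
               s[[1]][[1]]["g", "F value"], tolerance = 1e-8)
})

test_that("mixed RM-ANOVA matches the projection oracle on random designs", {
  set.seed(21)
  for (r in 1:15) {
    d <- random_balanced_design()
    at <- rm_anova_mixed(d, value = "y", group = "g", subject = "s",
                         time = "t")
    orc <- rm_anova_glm_oracle(d)
    expect_equal(at$F[at$effect == "group"], orc$F_group,
                 tolerance = 1e-8)
    expect_equal(at$F[at$effect == "time"], orc$F_time, tolerance = 1e-8)
    expect_equal(at$F[at$effect == "group:time"], orc$F_inter,
                 tolerance = 1e-8)
  }
})

test_that("mixed RM-ANOVA invariances and guards", {
  set.seed(8)
  d <- random_balanced_design()
  at1 <- rm_anova_mixed(d, value = "y", group = "g", subject = "s",
                        time = "t")
  d2 <- d; d2$y <- d$y + 5
  at2 <- rm_anova_mixed(d2, value = "y", group = "g", subject = "s",
                        time = "t")
  expect_equal(at1$F, at2$F, tolerance = 1e-10)
  # identical groups: between-group SS and F are zero
  dd <- expand.grid(s = 1:4, t = 1:3)
  dd$g <- ifelse(dd$s <= 2, "A", "B")
  dd$y <- c(3, 5, 3, 5)[dd$s] + dd$t  # group B copies group A exactly
  at <- rm_anova_mixed(dd, value = "y", group = "g", subject = "s",
                       time = "t")
  expect_equal(at$SS[at$effect == "group"], 0, tolerance = 1e-10)
  expect_equal(at$F[at$effect == "group"], 0, tolerance = 1e-10)
  # unbalanced time grids are rejected
  dbad <- d[-1, ]
  expect_error(rm_anova_mixed(dbad, value = "y", group = "g",
                              subject = "s", time = "t"), "unbalanced")
  # zero-variance error stratum reported, F undefined
  dz <- expand.grid(s = 1:4, t = 1:2)
  dz$g <- ifelse(dz$s <= 2, "A", "B")
  dz$y <- ifelse(dz$g == "A", 1, 2) + 0.5 * dz$t
  atz <- rm_anova_mixed(dz, value = "y", group = "g", subject = "s",
                        time = "t")
  expect_true(is.na(atz$F[atz$effect == "group"]))
  expect_true("subject_within_group" %in% attr(atz, "zero_variance"))
})

test_that("bonferroni adjustment caps at one", {
  expect_equal(bonferroni_adjust(0.01, 3), 0.03)
  expect_equal(bonferroni_adjust(0.5, 4), 1)
  expect_equal(bonferroni_adjust(0, 10), 0)
  expect_equal(bonferroni_adjust(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni_adjust(1.2, 2), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(0.1, 0.2), 1), "family size")
})

test_that("one-way ANOVA reproduces the hand SS decomposition", {
  # groups {1,2,3},{2,3,4},{6,7,8}: SSB = 42, SSW = 6 -> F = 21
  r <- one_way_anova(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(6, 7, 8)))
  expect_equal(r$F, 21, tolerance = 1e-10)
  expect_equal(r$p, stats::pf(21, 2, 6, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_true(is.na(one_way_anova(list(a = c(1, 1), b = c(1, 1)))$F))
  rz <- one_way_anova(list(a = c(0, 0), b = c(1, 1)))
  expect_identical(rz$F, Inf)
  expect_identical(rz$p, 0)
  expect_error(one_way_anova(list(a = 1, b = c(1, 2))), "at least 2 values")
})

test_that("Tukey HSD collapses to the pooled t-test for two groups", {
  set.seed(12)
  a <- stats::rnorm(6, 0, 1); b <- stats::rnorm(7, 0.8, 1)
  tk <- tukey_hsd(list(a = a, b = b))
  tt <- stats::t.test(b, a, var.equal = TRUE)$p.value
  expect_equal(tk$p_adj, tt, tolerance = 1e-8)  # q = t * sqrt(2) identity
  same <- tukey_hsd(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_true(all(abs(same$p_adj - 1) < 1e-8))
  set.seed(13)
  far <- tukey_hsd(list(a = stats::rnorm(5, 0, 0.1),
                        b = stats::rnorm(5, 10, 0.1),
                        c = stats::rnorm(5, 20, 0.1)))
  expect_true(all(far$p_adj < 1e-6))
})

test_that("normality and equal-variance diagnostics behave", {
  # equal spread around group medians: Brown-Forsythe F near zero
  g1 <- c(1, 2, 3, 4, 5); g2 <- c(101, 102, 103, 104, 105)
  expect_lt(variance_check(list(g1, g2))$statistic, 1e-10)
  set.seed(31)
  bf <- variance_check(list(stats::rnorm(20, 0, 1),
                            stats::rnorm(20, 0, 10)))
  expect_lt(bf$p, 0.01)
  # Shapiro-Wilk holds its size on normal draws
  set.seed(32)
  ps <- replicate(100, normality_check(stats::rnorm(50))$p)
  expect_gte(mean(ps > 0.05), 0.90)
  expect_error(normality_check(rep(1, 10)), "constant")
})

test_that("linear regression and R-squared conventions", {
  x <- 1:10
  r <- linear_r2(x, 2 * x + 1)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  expect_equal(r$intercept, 1, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  # hand-computed least squares: slope 0.5, R^2 = 0.25
  r2 <- linear_r2(c(1, 2, 3), c(1, 3, 2))
  expect_equal(r2$slope, 0.5, tolerance = 1e-12)
  expect_equal(r2$r_squared, 0.25, tolerance = 1e-12)
  expect_equal(linear_r2(1:5, rep(3, 5))$r_squared, 0)
  expect_error(linear_r2(rep(1, 5), 1:5), "constant")
})

test_that("suspect screening is strict and monotone in the threshold", {
  sm <- data.frame(particle_id = c("a", "b", "c", "d"),
                   final_deformation = c(5, 9, 25, 8.1))
  expect_setequal(screen_suspects(sm, 8.1), c("b", "c"))  # 8.1 not suspect
  expect_setequal(screen_suspects(sm, 0), c("a", "b", "c", "d"))
  sm0 <- data.frame(particle_id = "x", final_deformation = 0)
  expect_length(screen_suspects(sm0, 8.1), 0)
  set.seed(41)
  smr <- data.frame(particle_id = as.character(1:50),
                    final_deformation = stats::runif(50, 0, 40))
  ths <- sort(stats::runif(6, 0, 40))
  sets <- lapply(ths, function(th) screen_suspects(smr, th))
  for (i in 2:length(sets))
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("similarity test tracks group equality", {
  pet <- material_presets()$PET
  # identical profiles on both sides: between-group SS exactly zero
  a <- generate_profile_table(pet, 3, ref_times, seed = 4)
  b <- a; b$particle_id <- paste0("dup_", b$particle_id)
  sim0 <- similarity_to_reference(a, b)
  expect_equal(sim0$anova$SS[sim0$anova$effect == "group"], 0,
               tolerance = 1e-9)
  # strong alternative rejects almost always
  shifted <- material_params("shifted", pet$crystallinity,
                             min(0.95, pet$max_shrinkage + 0.3), pet$rate)
  set.seed(42)
  rej <- replicate(40, {
    s <- sample.int(1e7, 1)
    ref <- generate_profile_table(pet, 5, ref_times, seed = s)
    sus <- generate_profile_table(shifted, 10, ref_times, seed = s + 1)
    sus$particle_id <- paste0("s_", sus$particle_id)
    similarity_to_reference(sus, ref)$p_value < 0.01
  })
  expect_gte(mean(rej), 0.9)
  # singletons are not assessable
  single <- generate_profile_table(pet, 1, ref_times, seed = 9)
  expect_error(similarity_to_reference(single, a), "fewer than 2")
})

test_that("classification calls nothing on a non-deforming sample", {
  lib <- build_reference_library(seed = 77)
  hd <- generate_blinded_profiles(c(HDPE = 10), seed = 6)
  rep_ <- classify_sample(hd$profiles, lib)
  expect_true(all(rep_$results$n_suspect == 0))
  expect_true(all(!rep_$results$present))
  expect_error(classify_sample(hd$profiles[0, ], lib), "empty sample")
})

test_that("doubled profile noise reproduces the false-PVC failure mode", {
  # with measurement noise doubled, heavy-tailed PET particles cross the
  # PVC threshold and the under-powered similarity test can issue a false
  # PVC presence call on a PET+algae sample
  noisy <- material_presets()
  for (nm in names(noisy)) noisy[[nm]]$profile_noise_sd <-
      2 * noisy[[nm]]$profile_noise_sd
  comp <- table1_compositions()$sample1
  false_pvc <- logical(25)
  for (s in 1:25) {
    lib <- build_reference_library(seed = 500 + s)
    b <- generate_blinded_profiles(comp, seed = 800 + s, presets = noisy)
    r <- classify_sample(b$profiles, lib)
    false_pvc[s] <- r$results$present[r$results$material == "PVC"]
  }
  expect_gte(sum(false_pvc), 1)
})
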