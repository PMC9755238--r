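test_that("paired t matches the hand-computed statistic", {
  # diffs (1, 2, 3): mean 2, sd 1, t = 2 / (1/sqrt(3)) = 3.464, df = 2
  first <- c(10, 20, 30)
  second <- c(11, 22, 33)
  res <- paired_t(first, second)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$mean_difference, 2)
  expect_equal(res$n_pairs, 3)
  # antisymmetry
  expect_equal(paired_t(second, first)$t, -res$t)
  expect_error(paired_t(first, first + 5), "zero-variance")
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("paired t recovers an injected session effect", {
  set.seed(10)
  first <- rnorm(600, 350, 50)
  second <- first + 95 + rnorm(600, 0, 30)
  res <- paired_t(first, second)
  expect_lt(abs(res$mean_difference - 95), 3 * 30 / sqrt(600))
  expect_lt(res$p, 1e-10)
})

test_that("mixed model reduces to OLS with one observation per subject", {
  co <- generate_cohort(cohort_spec(n_preterm = 40L, n_term = 0L),
                        seed = 12)
  # lme4 warns about the degenerate single-observation fit; the point of
  # the check is only that the fixed effects collapse to OLS
  mm <- suppressWarnings(
    fit_random_intercept_model(co, "claustrum_volume_mean",
                               fixed_terms = c("scan_age", "sex")))
  ols <- fit_glm(co, "claustrum_volume_mean", group = NULL,
                 covariates = c("scan_age", "sex"))
  expect_equal(mm$fixed$estimate, ols$coefficients$estimate,
               tolerance = 1e-4)
})

test_that("mixed model recovers the generative slope and variance", {
  slopes_hat <- ses <- numeric(20)
  ri <- numeric(20)
  for (i in 1:20) {
    lg <- generate_longitudinal_cohort(
      longitudinal_spec(), effect_params(),
      slopes = c(claustrum_volume_right = 16.6,
                 claustrum_volume_left = 16.6),
      seed = 100 + i)
    mm <- fit_random_intercept_model(lg, "claustrum_volume_mean")
    row <- mm$fixed[mm$fixed$term == "scan_age", ]
    slopes_hat[i] <- row$estimate
    ses[i] <- row$se
    ri[i] <- mm$intercept_sd
  }
  expect_lt(abs(mean(slopes_hat) - 16.6),
            3 * sd(slopes_hat) / sqrt(length(slopes_hat)))
  # default intercept-SD fraction 0.5 of the marginal SD ~ 57 mm^3/2 sides
  expect_gt(mean(ri), 0)

  # boundary: zero within-subject intercept SD is estimated near zero
  spec0 <- longitudinal_spec()
  spec0$intercept_sd <- 0
  lg0 <- generate_longitudinal_cohort(spec0, seed = 55)
  mm0 <- fit_random_intercept_model(lg0, "claustrum_volume_mean")
  expect_lt(mm0$intercept_sd, 0.5 * mm0$residual_sd)
})

test_that("greedy matching follows the minimal-gap rule", {
  pt <- data.frame(subject_id = c("p1", "p2"), scan_age = c(40, 41))
  ft <- data.frame(subject_id = c("t1", "t2", "t3"),
                   scan_age = c(39.9, 40.8, 41.2))
  m <- match_controls(pt, ft)
  expect_equal(m$pairs$term_id, c("t1", "t2"))
  expect_equal(m$pairs$gap, c(0.1, 0.2), tolerance = 1e-9)
  expect_equal(m$unmatched_terms, "t3")

  # identical age lists: every gap is zero
  ft2 <- data.frame(subject_id = c("t1", "t2"), scan_age = c(40, 41))
  expect_equal(match_controls(pt, ft2)$pairs$gap, c(0, 0))

  # ties resolved to the smaller term scan age then the smaller id
  ft3 <- data.frame(subject_id = c("tb", "ta"), scan_age = c(40.5, 39.5))
  m3 <- match_controls(pt[1, ], ft3)
  expect_equal(m3$pairs$term_id, "ta")

  expect_error(match_controls(rbind(pt, pt), ft2), "smaller")
  expect_warning(match_controls(data.frame(subject_id = "p9",
                                           scan_age = 30),
                                ft),
                 "outside")
})

test_that("matching never reuses controls and ignores row order", {
  co <- generate_cohort(cohort_spec(n_preterm = 60L, n_term = 200L),
                        seed = 19)
  pt <- co[co$group == "preterm", ]
  ft <- co[co$group == "term", ]
  m1 <- suppressWarnings(match_controls(pt, ft))
  expect_equal(anyDuplicated(m1$pairs$term_id), 0)
  expect_equal(nrow(m1$pairs), nrow(pt))
  set.seed(2)
  m2 <- suppressWarnings(match_controls(pt[sample(nrow(pt)), ],
                                        ft[sample(nrow(ft)), ]))
  expect_equal(m1$pairs, m2$pairs)
})

test_that("matched synthetic groups are age-equivalent", {
  co <- generate_cohort(cohort_spec(n_preterm = 83L, n_term = 377L),
                        seed = 23)
  pt <- co[co$group == "preterm", ]
  ft <- co[co$group == "term", ]
  m <- suppressWarnings(match_controls(pt, ft))
  expect_lt(abs(mean(m$pairs$preterm_age) - mean(m$pairs$term_age)), 0.1)
})
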