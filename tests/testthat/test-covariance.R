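test_that("Fisher transformation behaves as atanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_error(fisher_z(1), "< 1")
})

test_that("region correlations equal the covariance/SD ratio", {
  regions <- data.frame(region = c("a", "b"), class = "cortical_gm")
  tab <- data.frame(claustrum_md = c(1.0, 1.1, 1.2, 1.3, 1.45),
                    a_md = c(2.0, 2.3, 2.1, 2.6, 2.7),
                    b_md = 3 * c(1.0, 1.1, 1.2, 1.3, 1.45))
  r <- region_claustrum_correlations(tab, "md", regions)
  byhand <- cov(tab$claustrum_md, tab$a_md) /
    (sd(tab$claustrum_md) * sd(tab$a_md))
  expect_equal(unname(r["a"]), byhand)
  # a scaled copy of the claustrum column correlates perfectly
  expect_equal(unname(r["b"]), 1)
  # zero-variance column flags as missing
  tab$a_md <- 2
  expect_true(is.na(region_claustrum_correlations(tab, "md", regions)["a"]))
  expect_error(region_claustrum_correlations(tab[1:3, ], "md", regions),
               "at least 4")
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(rep(0.2, 7)), rep(0.2, 7))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p - 1e-12))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("the two-sample z statistic follows the closed form", {
  co <- generate_cohort(cohort_spec(n_preterm = 72L, n_term = 72L),
                        seed = 41)
  spec <- regional_cov_spec()
  rt <- generate_regional_table(spec, co[co$group == "term", ], seed = 1)
  rp <- generate_regional_table(spec, co[co$group == "preterm", ], seed = 2)
  cc <- compare_covariance(rt, rp, "fa")
  se <- sqrt(1 / (72 - 3) + 1 / (72 - 3))
  expect_equal(cc$z_diff, (cc$z_preterm - cc$z_term) / se)
  expect_equal(cc$z_term, atanh(cc$r_term))
  expect_equal(cc$p, 2 * pnorm(-abs(cc$z_diff)))
  expect_true(all(cc$q >= cc$p))
  expect_equal(cc$significant, cc$q < 0.05)
  # worked magnitude: z 0.8 vs 0.3 at n = 72 per group gives Z = 2.937
  expect_equal((0.8 - 0.3) / se, 2.9368, tolerance = 1e-4)

  # identical tables give Z = 0 and p = 1 everywhere
  cc0 <- compare_covariance(rt, rt, "fa")
  expect_true(all(cc0$z_diff == 0))
  expect_true(all(cc0$p == 1))

  # mismatched region sets are rejected with the difference listed
  rt2 <- rt
  names(rt2)[names(rt2) == "insula_left_fa"] <- "nonsense_fa"
  expect_error(compare_covariance(rt2, rp, "fa"), "insula_left")
})

test_that("comparison is invariant to column order and rescaling", {
  co <- generate_cohort(cohort_spec(n_preterm = 40L, n_term = 40L),
                        seed = 43)
  spec <- regional_cov_spec()
  rt <- generate_regional_table(spec, co[co$group == "term", ], seed = 3)
  rp <- generate_regional_table(spec, co[co$group == "preterm", ], seed = 4)
  base <- compare_covariance(rt, rp, "md")
  rt_shuffled <- rt[, c(1:2, sample(3:ncol(rt)))]
  rt_shuffled$insula_left_md <- rt_shuffled$insula_left_md * 40 - 7
  again <- compare_covariance(rt_shuffled, rp, "md")
  expect_equal(as.data.frame(base), as.data.frame(again),
               tolerance = 1e-12)
})

test_that("tissue summaries aggregate z-scores per class", {
  entries <- data.frame(
    region = c("r1", "r2", "r3", "s1"),
    class = c(rep("cortical_gm", 3), "subcortical_gm"),
    metric = "md",
    z_term = c(0.1, 0.2, 0.3, 0.9),
    z_preterm = c(0.0, 0.1, 0.2, 0.4),
    significant = c(FALSE, TRUE, FALSE, FALSE))
  s <- tissue_summary(entries)
  ctx_t <- s[s$class == "cortical_gm" & s$group == "term", ]
  expect_equal(ctx_t$mean_z, 0.2)
  expect_equal(ctx_t$sd_z, 0.1)
  expect_equal(ctx_t$n_significant, 1)
  expect_equal(ctx_t$n_total, 3)
  sub <- s[s$class == "subcortical_gm" & s$group == "preterm", ]
  expect_equal(sub$mean_z, 0.4)
  expect_equal(sub$n_significant, 0)
  bad <- entries
  bad$class[1] <- "elsewhere"
  expect_error(tissue_summary(bad), "tissue class")
})

test_that("perfect correlations are clamped before transforming", {
  regions <- data.frame(region = "a", class = "cortical_gm")
  tab <- data.frame(claustrum_md = c(1, 2, 3, 4, 5),
                    a_md = c(1, 2, 3, 4, 5) * 2)
  tabb <- data.frame(claustrum_md = c(1.0, 2.1, 2.9, 4.2, 5.1),
                     a_md = c(2.2, 1.9, 3.3, 4.0, 4.8))
  expect_warning(cc <- compare_covariance(tab, tabb, "md", regions),
                 "clamped")
  expect_true(is.finite(cc$z_term))
})
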