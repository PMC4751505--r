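test_that("Bliss CI follows its algebra", {
  expect_equal(bliss_ci(0.3, 0.4, 0.58), 1)              # exact independence
  expect_equal(bliss_ci(0.5, 0.5, 0.9), 0.75 / 0.9)      # synergy, < 1
  expect_equal(bliss_ci(0.4, 0, 0.2), 2)                 # single-agent limit
  expect_true(is.na(bliss_ci(0.3, 0.3, 0)))              # undefined combined
  expect_warning(ci <- bliss_ci(-0.2, 0.4, 0.5), "Negative")
  expect_equal(ci, 0.4 / 0.5)
  # monotone: larger combined effect means smaller CI
  cis <- bliss_ci(0.3, 0.3, c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(cis) < 0))
})

test_that("Bliss identity holds for independent multiplicative survival", {
  # construct outcomes with T_ab/T_sx = (T_a/T_sx)(T_b/T_sx)
  e_a <- 0.37; e_b <- 0.22
  e_ab <- 1 - (1 - e_a) * (1 - e_b)
  expect_equal(bliss_ci(e_a, e_b, e_ab), 1, tolerance = 1e-12)
})

test_that("all 16 regimens are predicted with SX as the zero-inhibition anchor", {
  oc <- predict_all_regimens(default_truth())
  expect_equal(nrow(oc), 16)
  expect_equal(oc$inhibition_I[oc$regimen == "SX"], 0)
  expect_equal(oc$inhibition_II[oc$regimen == "SX"], 0)
  expect_true(all(oc$type_I >= 0 & oc$type_II >= 0))
})

test_that("rankings are stable, tie-flagged, and monotone-transform invariant", {
  oc <- predict_all_regimens(default_truth())
  rk <- rank_regimens(oc, "I")
  expect_equal(rk$rank, 1:16)
  expect_true(all(diff(rk$inhibition) <= 0))
  # invariance to a strictly monotone transform of the outcome
  oc2 <- oc
  oc2$inhibition_I <- 100 * plogis(oc$inhibition_I / 25)
  expect_equal(rank_regimens(oc2, "I")$regimen, rk$regimen)
  # exact ties resolve lexicographically and are flagged
  oc3 <- oc
  oc3$inhibition_I <- 1
  rk3 <- rank_regimens(oc3, "I")
  expect_true(all(rk3$tied))
  expect_equal(rk3$regimen, sort(oc$regimen))
})

test_that("the CI matrix is symmetric with blanks exactly on overlapping pairs", {
  oc <- predict_all_regimens(default_truth())
  cim <- ci_matrix(oc, "I")
  m <- cim$matrix
  expect_equal(dim(m), c(15, 15))
  expect_equal(m, t(m))
  expect_true(all(is.na(diag(m))))
  groups <- treatment_groups()
  flags <- as.matrix(groups[, c("cx", "v", "ai", "ar")])
  for (i in seq_len(nrow(groups))) {
    for (j in seq_len(nrow(groups))) {
      overlapping <- any(flags[i, ] & flags[j, ])
      expect_equal(is.na(m[i, j]) || !overlapping, TRUE)
      if (overlapping) expect_true(is.na(m[i, j]))
    }
  }
  # a specific overlap: (CX + V) with V is blank
  expect_true(is.na(m["(CX + V)", "V"]))
  # disjoint pairs are populated
  expect_false(is.na(m["(CX + V)", "AR"]))
})

test_that("component summaries cover 8 regimens each and filter to CI < 1", {
  oc <- predict_all_regimens(default_truth())
  cs <- component_summary(oc, ci_matrix(oc, "I"))
  expect_equal(nrow(cs), 4)
  expect_true(all(cs$n_regimens == 8))
  # hand-check the mean inhibition of AR against a direct computation
  regs <- enumerate_regimens()
  ar_mean <- mean(oc$inhibition_I[oc$regimen %in% regs$label[regs$ar]])
  expect_equal(cs$mean_inhibition[cs$component == "AR"], ar_mean)
  # synergy means are NA when no pair is synergistic
  oc_null <- oc
  oc_null$inhibition_I <- 0  # no effects anywhere -> CI undefined/blank
  cs_null <- component_summary(oc_null, ci_matrix(oc_null, "I"))
  expect_true(all(is.na(cs_null$synergy_unmixed)))
})

test_that("component ranks extract within-size positions", {
  oc <- predict_all_regimens(default_truth())
  cr <- component_ranks(oc, "AR", "I")
  expect_equal(sort(unique(cr$n_components)), 1:3)
  expect_equal(sum(cr$n_components == 1), 1)
  expect_equal(sum(cr$n_components == 2), 3)
  expect_equal(sum(cr$n_components == 3), 3)
  expect_true(all(cr$rank_within_size >= 1))
})

test_that("pearson_r and t_test agree with hand calculations", {
  p <- pearson_r(1:5, 2 * (1:5) + 3)
  expect_equal(p$r, 1)
  expect_equal(pearson_r(1:5, -(1:5))$r, -1)
  tt <- t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 1)
  tt2 <- t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt2$t, -3.674, tolerance = 1e-3)
  expect_equal(tt2$df, 4)
  expect_equal(tt2$p_value, 0.0214, tolerance = 1e-2)
  # one-tailed p is half the two-tailed p in the matching direction
  one <- t_test(c(4, 5, 6), c(1, 2, 3), tails = "one")
  expect_equal(one$p_value, t_test(c(4, 5, 6), c(1, 2, 3))$p_value / 2)
  expect_error(t_test(1, c(1, 2)), ">= 2")
})

test_that("local sensitivity is zero for decoupled parameters and linear on stubs", {
  tv <- truth_values()
  # decouple the regulatory-DC branch: alpha_Dr = zeta = 0 makes delta_Dr inert
  tv2 <- tv
  tv2[c("alpha_Dr", "zeta")] <- 0
  sens <- local_sensitivity(parameter_table(values = tv2), conditions = "CX")
  dDr <- sens$sensitivity[sens$name == "delta_Dr"]
  expect_equal(dDr, rep(0, 2), tolerance = 1e-6)
  # 5% perturbation of an exactly proportional outcome reads 5%
  y <- function(p) 3 * p
  p0 <- 2
  expect_equal(100 * (y(p0 * 1.05) - y(p0)) / y(p0), 5)
  # sensitivity/perturbation converges to the normalized forward difference
  s5 <- local_sensitivity(default_truth(), 0.05, conditions = "CX")
  s1 <- local_sensitivity(default_truth(), 0.01, conditions = "CX")
  r5 <- s5$sensitivity[s5$name == "rho_R" & s5$outcome_type == "I"] / 5
  r1 <- s1$sensitivity[s1$name == "rho_R" & s1$outcome_type == "I"] / 1
  expect_equal(r5, r1, tolerance = 0.15)
  expect_error(local_sensitivity(default_truth(), -0.1), "positive")
})

test_that("sensitivity table has the full parameter x condition x type layout", {
  sens <- local_sensitivity(default_truth(), conditions = c("SX", "CX"))
  expect_equal(nrow(sens), 25 * 2 * 2)
  expect_true(all(is.finite(sens$sensitivity)))
})
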