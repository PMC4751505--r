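test_that("state vector has 15 components with regimen-set initial values", {
  y0 <- initial_state("SX")
  expect_length(y0, 15)
  expect_equal(unname(y0["A"]), 1)
  expect_true(all(y0[c("V", "B_I", "B_R")] == 0))
  y1 <- initial_state("CX + V + AR")
  expect_equal(unname(y1[c("V", "B_I", "B_R")]), c(1, 0, 1))
  expect_true(all(y1[5:15] == 1))  # all biological states start at 1
})

test_that("parameter table has 25 positive estimated entries within bounds", {
  truth <- default_truth()
  est <- truth[truth$estimated, ]
  expect_equal(nrow(est), 25)
  expect_setequal(est$index, 1:25)
  expect_true(all(est$value > 0))
  expect_true(all(est$value >= est$lower & est$value <= est$upper))
  # positions 4 and 5 are the CRPC proliferation and apoptosis rates
  expect_equal(est$name[match(4:5, est$index)], c("rho_R", "delta_R"))
})

test_that("null rates give a null derivative and decoupled cases behave", {
  nm <- default_truth()$name
  zero <- parameter_table(values = setNames(rep(0, 33), nm))
  zero$value[zero$name == "kappa"] <- 20  # capacity must stay positive
  s <- initial_state("CX + V + AR")
  expect_equal(unname(tumor_immune_rhs(s, 0, zero, "CX + V + AR")),
               rep(0, 15))
  # SX: no castration indicator, androgen is flat
  d_sx <- tumor_immune_rhs(initial_state("SX"), 0, default_truth(), "SX")
  expect_equal(unname(d_sx["A"]), 0)
  # empty tumor: no antigen source, functional DCs decay
  truth <- default_truth()
  s2 <- initial_state("SX")
  s2[c("S", "R", "Ag", "V")] <- 0
  d <- tumor_immune_rhs(s2, 0, truth, "SX")
  expect_equal(unname(d["Ag"]), 0)
  delta_D <- truth$value[truth$name == "delta_D"]
  expect_equal(unname(d["D_L"]), -delta_D * s2[["D_L"]])
  # non-finite state is rejected naming the offender
  s3 <- initial_state("SX"); s3["C_L"] <- NaN
  expect_error(tumor_immune_rhs(s3, 0, truth, "SX"), "C_L")
})

test_that("compiled and reference right-hand sides integrate identically", {
  for (rg in c("SX", "CX + V + AR")) {
    a <- simulate_model(default_truth(), rg, times = seq(0, 5, by = 0.5))
    b <- simulate_model(default_truth(), rg, times = seq(0, 5, by = 0.5),
                        compiled = FALSE)
    expect_equal(as.data.frame(a), as.data.frame(b), tolerance = 1e-6)
  }
})

test_that("decoupled treatment variables match analytic exponentials", {
  tr <- simulate_model(default_truth(), "CX + V + AI + AR")
  t <- tr$time
  expect_equal(tr$A, exp(-2.0 * t), tolerance = 1e-5)
  expect_equal(tr$V, exp(-1.0 * t), tolerance = 1e-5)
  expect_equal(tr$B_I, exp(-1.0 * t), tolerance = 1e-5)
  expect_equal(tr$B_R, exp(-1.0 * t), tolerance = 1e-5)
  # under SX the treatment variables are identically zero
  tr0 <- simulate_model(default_truth(), "SX")
  expect_true(all(tr0$V == 0) && all(tr0$B_I == 0) && all(tr0$B_R == 0))
  expect_equal(tr0$A, rep(1, nrow(tr0)), tolerance = 1e-6)
})

test_that("CX-only androgen decay matches the closed form at t = 1", {
  # with all couplings irrelevant to A, A(t) = exp(-delta_A t); delta_A = 2
  tr <- simulate_model(default_truth(), "CX", times = c(0, 1, 2.5, 5))
  expect_equal(tr$A[2], exp(-2), tolerance = 1e-5)
  expect_equal(tr$A[2], 0.13534, tolerance = 1e-4)
})

test_that("all rates zero freezes every state", {
  zero <- parameter_table(values = setNames(rep(0, 33), default_truth()$name))
  zero$value[zero$name == "kappa"] <- 20
  tr <- simulate_model(zero, "CX + V + AR")
  expect_true(attr(tr, "valid"))
  for (nm in setdiff(names(tr), "time")) {
    expect_equal(tr[[nm]], rep(tr[[nm]][1], nrow(tr)))
  }
})

test_that("observables are relative, equal 1 at t = 0, and tumor is (S+R)/initial", {
  tr <- simulate_model(default_truth(), "CX + V")
  obs <- observe(tr)
  expect_setequal(unique(obs$observable),
                  c("Tumor", "CTL-P", "Treg-P", "CTL-L", "Treg-L"))
  at0 <- obs$value[obs$time == 0]
  expect_equal(at0, rep(1, 5))
  tum5 <- obs$value[obs$observable == "Tumor" & obs$time == 5]
  expect_equal(tum5, (tr$S[nrow(tr)] + tr$R[nrow(tr)]) / (tr$S[1] + tr$R[1]))
})

test_that("outcomes follow their definitions on analytic tumor curves", {
  tr <- simulate_model(default_truth(), "SX")
  # constant tumor: both outcomes equal and 1
  zero <- parameter_table(values = setNames(rep(0, 33), default_truth()$name))
  zero$value[zero$name == "kappa"] <- 20
  trc <- simulate_model(zero, "SX")
  oc <- outcomes(trc)
  expect_equal(oc$type_I, 1)
  expect_equal(oc$type_II, 1)
  # exponential tumor: check against closed forms by forging S = exp(-t), R = 0
  fake <- simulate_model(zero, "SX", step = 0.01)
  fake$S <- exp(-fake$time)
  fake$R <- 0 * fake$time
  expect_equal(outcome_instantaneous(fake), exp(-5), tolerance = 1e-6)
  expect_equal(outcome_average(fake), (1 - exp(-5)) / 5, tolerance = 1e-4)
  # linear tumor, Tumor(t) = t on (0, 5]: average is 2.5
  fake$S <- fake$time
  fake$R <- fake$time
  fake$S[1] <- 1; fake$R[1] <- 1  # S(0)+R(0) = 2, so Tumor(t) = 2t/2 = t
  expect_equal(outcome_average(fake), 2.5, tolerance = 1e-2)
  expect_equal(outcome_instantaneous(fake), 5)
})

test_that("outcome errors and horizon checks fire", {
  short <- simulate_model(default_truth(), "SX", horizon = 3, times = seq(0, 3, 0.5))
  expect_error(outcome_instantaneous(short), "5 weeks")
  expect_error(outcome_average(short), "5 weeks")
})

test_that("percent inhibition follows its definition and rejects bad controls", {
  expect_equal(percent_inhibition(1, 1), 0)
  expect_equal(percent_inhibition(0, 2), 100)
  expect_equal(percent_inhibition(3, 2), -50)
  expect_error(percent_inhibition(1, 0), "positive")
  expect_error(percent_inhibition(1, -2), "positive")
})

test_that("outcome_average converges under grid refinement", {
  o1 <- outcome_average(simulate_model(default_truth(), "CX + V", step = 0.1))
  o2 <- outcome_average(simulate_model(default_truth(), "CX + V", step = 0.05))
  expect_lt(abs(o2 - o1) / o2, 0.001)
})

test_that("states remain non-negative across random parameter draws", {
  set.seed(421)
  regs <- enumerate_regimens()$label
  n_valid <- 0
  for (i in 1:12) {
    vals <- truth_values() * exp(rnorm(25, 0, 0.4))
    p <- parameter_table(values = vals)
    tr <- simulate_model(p, sample(regs, 1))
    if (isTRUE(attr(tr, "valid"))) {
      n_valid <- n_valid + 1
      expect_gte(min(as.matrix(tr[, -1])), 0)
    }
  }
  expect_gt(n_valid, 0)
})

test_that("a regimen is invariant to the efficiency constants of absent treatments", {
  p1 <- default_truth()
  p2 <- parameter_table(values = c(truth_values(),
                                   kappa_AI = 7, kappa_AR = 9, delta_A = 5))
  a <- simulate_model(p1, "V", times = c(0, 2.5, 5))
  b <- simulate_model(p2, "V", times = c(0, 2.5, 5))
  expect_equal(as.matrix(a), as.matrix(b), tolerance = 1e-8)
})

test_that("raising the CTL kill rate never increases tumor size at 5 weeks", {
  tv <- truth_values()
  tums <- vapply(c(0.5, 1, 1.5, 2.5), function(f) {
    tv2 <- tv; tv2["eta_S"] <- tv2["eta_S"] * f
    outcome_instantaneous(simulate_model(parameter_table(values = tv2), "CX + V"))
  }, numeric(1))
  expect_true(all(diff(tums) <= 1e-8))
})
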