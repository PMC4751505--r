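test_that("SSE objective matches hand arithmetic and is additive over boxes", {
  # toy dataset: model values replaced by data offsets of known size
  ref <- model_observable_table(default_truth())
  pick <- function(cond, obs, t) ref$value[ref$condition == cond &
                                             ref$observable == obs &
                                             ref$time_weeks == t]
  ds <- toy_dataset(values = c(pick("SX", "Tumor", 2.5) + 2,   # residual 2
                               pick("SX", "CTL-P", 5) + 0.5,   # residual .5
                               pick("CX", "Tumor", 5) + 1))    # residual 1
  expect_equal(sse_objective(default_truth(), ds), 4 + 0.25 + 1,
               tolerance = 1e-6)
  # dropping the CX condition drops exactly its contribution
  ds_sx <- validate_dataset(ds[ds$condition == "SX", ])
  expect_equal(sse_objective(default_truth(), ds_sx), 4.25, tolerance = 1e-6)
  expect_error(sse_objective(default_truth(), ds[0, ]), "empty")
})

test_that("the GA minimizes the sphere function and keeps elitist traces", {
  f <- function(x) sum(x^2)
  fit <- ga_minimize(f, rep(-1, 5), rep(1, 5),
                     ga_config(generations = 100, population = 100, seed = 7))
  expect_lt(fit$value, 1e-3)
  expect_true(all(diff(fit$trace) <= 0))
  expect_length(fit$trace, 101)
  # determinism under a fixed seed
  fit2 <- ga_minimize(f, rep(-1, 5), rep(1, 5),
                      ga_config(generations = 100, population = 100, seed = 7))
  expect_identical(fit$par, fit2$par)
  expect_identical(fit$value, fit2$value)
  # different seeds explore differently
  fit3 <- ga_minimize(f, rep(-1, 5), rep(1, 5),
                      ga_config(generations = 100, population = 100, seed = 8))
  expect_false(identical(fit$par, fit3$par))
  expect_error(ga_minimize(f, rep(-1, 5), rep(1, 4), ga_config()), "equal length")
})

test_that("hypergrid enumeration gives the documented candidate counts", {
  expect_equal(nrow(hypergrid_enumerate(hyper_grid())), 243)
  single <- hyper_grid(generations = 50, population = 50, p_crossover = 0.9,
                       eta_crossover = 10, eta_mutation = 20)
  expect_equal(nrow(hypergrid_enumerate(single)), 1)
  four <- hyper_grid(generations = c(50, 100), population = c(50, 100),
                     p_crossover = 0.9, eta_crossover = 10, eta_mutation = 20)
  enum <- hypergrid_enumerate(four)
  expect_equal(nrow(enum), 4)
  expect_false(any(duplicated(enum[, -1])))
})

test_that("coordinate-wise selection picks dominating levels and breaks ties first", {
  grid <- hyper_grid(generations = c(10, 20), population = c(30, 40),
                     p_crossover = 0.9, eta_crossover = 10, eta_mutation = 20)
  enum <- hypergrid_enumerate(grid)
  # construct dominance: generations 20 and population 30 strictly better
  enum$error <- 1 + (enum$generations == 10) * 10 + (enum$population == 40) * 5
  sel <- select_hyperparameters(enum, grid)
  expect_equal(sel$generations, 20)
  expect_equal(sel$population, 30)
  # all-equal errors: first-listed level everywhere
  enum$error <- 1
  sel2 <- select_hyperparameters(enum, grid)
  expect_equal(sel2$generations, 10)
  expect_equal(sel2$population, 30)
  expect_error(select_hyperparameters(enum[-1, ], grid), "one error per")
})

test_that("mga_fit with a singleton grid reduces to its component GA runs", {
  ds <- noise_free_dataset()
  grid <- hyper_grid(generations = 10, population = 12, p_crossover = 0.9,
                     eta_crossover = 10, eta_mutation = 20)
  tmpl <- tight_template(2)
  fit <- mga_fit(ds, grid, replicates = 1, seed = 42, params = tmpl,
                 polish = FALSE)
  # reproduce the two deterministic GA runs (stage 1 + one replicate)
  seeds <- withr::with_seed(42, sample.int(.Machine$integer.max - 1L, 2))
  ctx <- prostimm:::make_fit_context(ds, tmpl)
  obj <- prostimm:::ctx_objective_log(ctx)
  runs <- lapply(seeds, function(s) {
    ga_minimize(obj, log10(ctx$lower), log10(ctx$upper),
                ga_config(generations = 10, population = 12, p_crossover = 0.9,
                          eta_crossover = 10, eta_mutation = 20, seed = s))
  })
  expect_equal(fit$objective, min(vapply(runs, `[[`, numeric(1), "value")))
  # best-of construction: objective never exceeds the stage-1 error of the
  # selected configuration
  expect_lte(fit$objective, fit$stage1$error[1])
  # determinism end to end
  fit2 <- mga_fit(ds, grid, replicates = 1, seed = 42, params = tmpl,
                  polish = FALSE)
  expect_equal(tidy(fit)$estimate, tidy(fit2)$estimate)
})

test_that("replicate fit objectives: the minimum is no worse than the median", {
  ds <- noise_free_dataset()
  grid <- hyper_grid(generations = 10, population = 12, p_crossover = 0.9,
                     eta_crossover = 10, eta_mutation = 20)
  fit <- mga_fit(ds, grid, replicates = 5, seed = 3, params = tight_template(2),
                 polish = FALSE)
  expect_lte(min(fit$replicate_objectives), median(fit$replicate_objectives))
  expect_equal(fit$objective, min(min(fit$replicate_objectives),
                                  fit$stage1$error[1]))
})

test_that("bootstrap CV matches hand statistics and thresholds at 1", {
  # CV uses the sample (n-1) standard deviation: {1,2,3} -> sd 1, mean 2
  x <- c(1, 2, 3)
  expect_equal(sd(x) / mean(x), 0.5)
  # identical estimates -> CV 0 -> identifiable; sd/mean > 1 -> flagged
  est <- matrix(c(rep(2, 5), c(0.1, 10, 0.2, 9, 0.1)), ncol = 2)
  cv <- apply(est, 2, sd) / colMeans(est)
  expect_equal(cv[1], 0)
  expect_gt(cv[2], 1)
})

test_that("within-box resampling preserves box sizes and draws from the box", {
  ds <- generate_dataset(seed = 5)
  res <- withr::with_seed(1, prostimm:::resample_within_boxes(ds))
  expect_equal(dataset_boxes(res), dataset_boxes(ds))
  joined <- dplyr::left_join(
    as.data.frame(res), as.data.frame(ds),
    by = c("condition", "observable", "time_weeks"),
    suffix = c("", "_orig"), relationship = "many-to-many")
  hit <- joined |>
    dplyr::group_by(condition, observable, time_weeks, replicate_id) |>
    dplyr::summarise(ok = any(abs(value - value_orig) < 1e-12), .groups = "drop")
  expect_true(all(hit$ok))
})

test_that("bootstrap identifiability runs end to end at reduced scale", {
  ds <- generate_dataset(noise = noise_model(sigma = 0.1, replicates = 4),
                         seed = 7)
  out <- bootstrap_identifiability(ds, tiny_config(), n_boot = 3, seed = 2,
                                   params = tight_template(2), polish = FALSE)
  expect_equal(nrow(out), 25)
  expect_true(all(is.finite(out$cv)))
  expect_identical(out$identifiable, out$cv <= 1)
  expect_equal(dim(attr(out, "estimates")), c(3, 25))
  expect_error(bootstrap_identifiability(ds, n_boot = 1), ">= 2")
})

test_that("the delta-method screen separates stiff from sloppy parameters", {
  ds <- noise_free_dataset()
  scr <- identifiability_screen(ds, default_truth())
  expect_equal(nrow(scr), 25)
  expect_true(all(scr$cv >= 0))
  # the antigen-scale pair is sloppy by construction (antigen unmeasured)
  expect_false(scr$identifiable[scr$name == "sigma_Ag"])
  expect_false(scr$identifiable[scr$name == "delta_Ag"])
  # the CRPC proliferation rate is well constrained by tumor data
  expect_true(scr$identifiable[scr$name == "rho_R"])
  expect_gt(sum(scr$identifiable), 5)
})
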