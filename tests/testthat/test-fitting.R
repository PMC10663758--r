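linear_curve <- function(times, slope = 5) {
  structure(data.frame(time = times,
                       glucose_conversion = slope * times,
                       xylose_conversion = NA_real_,
                       events_EG = 0, events_CBH = 0, events_BGL = 0,
                       events_XYL = 0),
            class = c("sacch_timecourse", "data.frame"))
}

test_that("the fit objective is the mean squared deviation", {
  sim <- linear_curve(seq(0, 4, by = 2))
  on_curve <- data.frame(time = c(1, 3), conversion = c(5, 15))
  expect_equal(series_variance(sim, on_curve), 0)
  shifted <- data.frame(time = c(1, 3), conversion = c(7, 17))
  expect_equal(series_variance(sim, shifted), 4)
  # hand-computed 3-point case: interpolated curve (5, 10, 15),
  # residuals (1, 1, -1), MSE = 1
  toy <- data.frame(time = 1:3, conversion = c(6, 11, 14))
  expect_equal(series_variance(sim, toy), 1)
  beyond <- data.frame(time = c(1, 9), conversion = c(5, 45))
  expect_error(series_variance(sim, beyond), "horizon")
})

test_that("R^2 follows its definition at the experimental points", {
  sim <- linear_curve(seq(0, 4, by = 2))
  perfect <- data.frame(time = 1:3, conversion = c(5, 10, 15))
  expect_equal(r_squared(sim, perfect), 1)
  # a curve equal to the experimental mean scores exactly zero
  flat <- linear_curve(c(0, 4), slope = 0)
  flat$glucose_conversion <- c(10, 10)
  centred <- data.frame(time = 1:3, conversion = c(5, 10, 15))
  expect_equal(r_squared(flat, centred), 0)
  # hand-computed: SS_res = 3, SS_tot = 294/9
  toy <- data.frame(time = 1:3, conversion = c(6, 11, 14))
  expect_equal(r_squared(sim, toy), 1 - 27 / 294)
  expect_error(r_squared(sim, data.frame(time = 1, conversion = 5)),
               "at least two")
  same <- data.frame(time = 1:3, conversion = c(7, 7, 7))
  expect_error(r_squared(sim, same), "zero variance")
})

test_that("proposals respect ranges, groups and the directed geometry", {
  cur <- c(a = 0.9, b = 10)
  # zero range: proposals identical to the current values
  props <- propose_subgenerations(cur, delta = 0, n_subsets = 4)
  for (p in props) expect_equal(p, cur)
  # a [0,1]-ranged parameter never exits its range over many draws
  set.seed(42)
  props <- propose_subgenerations(c(a = 0.9), delta = 1, n_subsets = 10000,
                                  lower = 0, upper = 1)
  vals <- vapply(props, `[[`, numeric(1), "a")
  expect_true(all(vals >= 0 & vals <= 1))
  expect_gt(max(vals), 0.99)   # clipping actually engaged
  # directed mode: proposal k = current + k * direction
  v <- c(a = 0.01, b = -1)
  props <- propose_subgenerations(cur, delta = 0.25, n_subsets = 3,
                                  direction = v)
  expect_equal(props[[1]], cur + v)
  expect_equal(props[[3]], cur + 3 * v)
})

test_that("fraction groups stay normalised through proposals", {
  doc <- demo_params()
  theta <- c("frac_cellulose@1" = 0.6, "frac_hemicellulose@1" = 0.25,
             "frac_lignin@1" = 0.15)
  renorm <- sacchsim:::.make_renormalizer(doc, names(theta))
  set.seed(7)
  props <- propose_subgenerations(theta, delta = 0.5, n_subsets = 200,
                                  lower = rep(0, 3), upper = rep(1, 3),
                                  renormalize = renorm)
  sums <- vapply(props, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-9))
  # partially fitted group: the unfitted member stays fixed
  theta2 <- c("frac_EG@1" = 0.25, "frac_CBH@1" = 0.45, "frac_BGL@1" = 0.15)
  renorm2 <- sacchsim:::.make_renormalizer(doc, names(theta2))
  out <- renorm2(c("frac_EG@1" = 0.5, "frac_CBH@1" = 0.5,
                   "frac_BGL@1" = 0.5))
  expect_equal(sum(out), 1 - doc$samples[[1]]$frac_XYL)
})

test_that("the generational search descends a quadratic surrogate", {
  fn <- function(p) sum((p - c(0.3, 0.7))^2)
  set.seed(11)
  res <- generational_search(c(x = 0.9, y = 0.1), fn,
                             lower = c(0, 0), upper = c(1, 1),
                             delta = 0.25, n_gens = 15, n_subsets = 6)
  expect_lt(res$value, fn(c(0.9, 0.1)) / 4)
  # accepted-generation best variance is non-increasing
  expect_true(all(diff(res$trace$seed_variance) <= 1e-12))
  # the reported optimum is the minimum over every evaluation
  expect_equal(res$value, min(res$evals$value))
  i_best <- which.min(res$evals$value)
  expect_equal(unname(res$params[i_best, ]), unname(res$par))
  # failing evaluations score +Inf and the search continues
  set.seed(12)
  flaky <- function(p) if (p[["x"]] < 0.5) stop("boom") else fn(p)
  ws <- capture_warnings(
    res2 <- generational_search(c(x = 0.9, y = 0.1), flaky,
                                lower = c(0, 0), upper = c(1, 1),
                                delta = 0.2, n_gens = 4, n_subsets = 4))
  expect_match(ws, "scored \\+Inf", all = TRUE)
  expect_true(is.finite(res2$value))
})

test_that("fit specification enforces the sample contract", {
  doc <- demo_params()
  ser <- data.frame(time = c(1, 2), conversion = c(5, 10))
  expect_error(fit_spec(doc, rep(list(list(glucose = ser)), 6)),
               "one and five")
  expect_error(fit_spec(doc, list(s1 = list(glucose = ser)),
                        fit_kinetic = "no_such"), "not fittable")
  expect_error(fit_spec(doc, list(s1 = list(glucose = ser)),
                        fit_config = "sample_name"), "not fittable")
  bad <- data.frame(time = c(2, 1), conversion = c(5, 10))
  expect_error(fit_spec(doc, list(s1 = list(glucose = bad))),
               "strictly increasing")
  expect_error(fit_spec(doc, list(s1 = list(glucose = ser)), t_end = 1),
               "cover the experimental")
})

test_that("fitting zero parameters returns the starting values", {
  doc <- quick_params(simulation = list(t_end = 4))
  ser <- data.frame(time = c(1, 4), conversion = c(5, 20))
  spec <- fit_spec(doc, list(sample_1 = list(glucose = ser)),
                   replicates = 1, seed = 2, t_end = 4)
  fit <- run_fit(spec)
  expect_length(coef(fit), 0)
  expect_equal(nrow(fit$trace), 1)
  expect_equal(fit$params$kinetic, doc$kinetic)
  expect_equal(fit$params$samples, doc$samples)
  expect_true(is.finite(fit$value))
})

test_that("kinetics are shared while configurations vary per sample", {
  doc <- quick_params(simulation = list(t_end = 4), n_samples = 2)
  ser <- data.frame(time = c(1, 4), conversion = c(5, 20))
  samples <- list(sample_1 = list(glucose = ser),
                  sample_2 = list(glucose = ser))
  spec <- fit_spec(doc, samples, fit_kinetic = "kcat_EG",
                   fit_config = "crystalline_frac_cellulose",
                   n_gens = 2, n_subsets = 2, replicates = 1, seed = 9,
                   t_end = 4)
  fit <- run_fit(spec)
  expect_setequal(names(coef(fit)),
                  c("kcat_EG", "crystalline_frac_cellulose@1",
                    "crystalline_frac_cellulose@2"))
  # one shared kinetic value lands in the document's kinetic section,
  # per-sample values in their own sections (distinct records)
  expect_equal(fit$params$kinetic$kcat_EG, unname(coef(fit)["kcat_EG"]))
  expect_equal(fit$params$samples[[1]]$crystalline_frac_cellulose,
               unname(coef(fit)["crystalline_frac_cellulose@1"]))
  expect_equal(fit$params$samples[[2]]$crystalline_frac_cellulose,
               unname(coef(fit)["crystalline_frac_cellulose@2"]))
  # determinism: the same spec reproduces the same result
  fit2 <- run_fit(spec)
  expect_equal(coef(fit), coef(fit2))
  expect_equal(fit$value, fit2$value)
  # residuals and fitted curves exist per series
  expect_named(residuals(fit), c("sample_1:glucose", "sample_2:glucose"))
})

test_that("fitted models predict new samples from their configuration", {
  doc <- quick_params(simulation = list(t_end = 4))
  ser <- data.frame(time = c(1, 4), conversion = c(5, 20))
  spec <- fit_spec(doc, list(sample_1 = list(glucose = ser)),
                   replicates = 1, seed = 2, t_end = 4)
  fit <- run_fit(spec)
  newcfg <- list(frac_cellulose = 0.6, frac_hemicellulose = 0.25,
                 frac_lignin = 0.15, crystalline_frac_cellulose = 0.1,
                 crystalline_frac_hemicellulose = 0.1,
                 species_preset = "demo")
  expect_error(predict(fit, list(newcfg[-1])), "missing required field")
  preds <- predict(fit, list(newcfg, newcfg, newcfg), seed = 4, t_end = 2,
                   replicates = 1)
  expect_length(preds, 3)
  for (p in preds) expect_s3_class(p, "sacch_timecourse")
})
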