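# synthetic daily modelling table with a known quadratic SST effect, a null
# bathymetry effect, and animal random intercepts
gen_daily_table <- function(seed, n_animals = 8, n_days = 50, b_sd = 0.3,
                            noise_sd = 0.3, effect = 0.4) {
  set.seed(seed)
  ids <- sprintf("a%02d", seq_len(n_animals))
  b <- rnorm(n_animals, 0, b_sd)
  do.call(rbind, lapply(seq_along(ids), function(i) {
    sst <- rnorm(n_days); bathy <- rnorm(n_days)
    data.frame(animal_id = ids[i],
               trip_id = paste0(ids[i], "_t", rep(1:2, length.out = n_days)),
               class = "pup", sst_C = sst, bathymetry_m = bathy,
               fpt = effect * (sst^2 - 1) + b[i] + rnorm(n_days, 0, noise_sd))
  }))
}

test_that("standardization stores an invertible transform and matches z-scores", {
  set.seed(20)
  d <- data.frame(a = rnorm(50, 100, 12), b = runif(50))
  s <- standardize(d, c("a", "b"))
  tr <- attr(s, "standardize_transform")
  expect_equal(mean(s$a), 0, tolerance = 1e-12)
  expect_equal(sd(s$a), 1, tolerance = 1e-12)
  expect_equal(unname(unstandardize(s$a, tr, "a")), d$a, tolerance = 1e-12)
  expect_equal(max(s$a), (max(d$a) - mean(d$a)) / sd(d$a))
  expect_error(standardize(data.frame(a = rep(3, 5)), "a"), "constant")
  expect_error(standardize(data.frame(a = c(1, NA, 2)), "a"), "non-finite")
})

test_that("collinearity screen reports offending pairs at the 0.8 threshold", {
  set.seed(21)
  d <- data.frame(x = rnorm(300), y = rnorm(300))
  expect_true(check_collinearity(d, c("x", "y"))$pass)
  d$z <- d$x
  cc <- check_collinearity(d, c("x", "y", "z"))
  expect_false(cc$pass)
  expect_equal(cc$offending$r, 1)
  # |r| exactly at the threshold passes (<=)
  d2 <- data.frame(x = c(1, 2, 3, 4), y = c(1, 2, 3, 4))
  d2$y <- d2$x * 0.8 + sqrt(1 - 0.64) * c(-1.5, 1.5, -1.5, 1.5) / sd(c(-1.5, 1.5, -1.5, 1.5)) * sd(d2$x)
  r <- cor(d2$x, d2$y)
  cc2 <- check_collinearity(d2, c("x", "y"), threshold = abs(r))
  expect_true(cc2$pass)
  expect_error(check_collinearity(d, "x"), "at least 2")
})

test_that("model fitting is deterministic and rejects non-identifiable specs", {
  d <- gen_daily_table(1, n_animals = 4, n_days = 30)
  f1 <- fit_gamm(d, habitat_spec("fpt", "sst_C"))
  f2 <- fit_gamm(d, habitat_spec("fpt", "sst_C"))
  expect_equal(f1$aic, f2$aic, tolerance = 1e-6)
  expect_true(is.finite(f1$aic))
  expect_error(fit_gamm(d, habitat_spec("fpt", "sst_C", by_class = TRUE)),
               "more than one class")
})

test_that("the fitted smooth recovers a known quadratic effect", {
  d <- gen_daily_table(2)
  f <- fit_gamm(d, habitat_spec("fpt", c("sst_C", "bathymetry_m")))
  cv <- smooth_curve(f, "sst_C")
  truth <- 0.4 * (cv$x^2 - 1)
  expect_gte(cor(cv$fit, truth), 0.9)
  # animal-intercept SD recovered within 50% relative error
  vc <- mgcv::gam.vcomp(f$model)
  sd_hat <- vc[grep("animal", rownames(vc)), "std.dev"]
  expect_lt(abs(sd_hat - 0.3) / 0.3, 0.5)
})

test_that("pure-noise responses yield smooth CIs covering zero", {
  set.seed(23)
  d <- gen_daily_table(3, effect = 0, b_sd = 0, noise_sd = 1)
  f <- fit_gamm(d, habitat_spec("fpt", "sst_C"))
  cv <- smooth_curve(f, "sst_C")
  cover <- mean(abs(cv$fit) <= 1.96 * cv$se)
  expect_gte(cover, 0.8)
})

test_that("fitted values are invariant to covariate standardization", {
  d <- gen_daily_table(4, n_animals = 4, n_days = 30)
  raw <- fit_gamm(d, habitat_spec("fpt", "sst_C"))
  ds <- standardize(d, "sst_C")
  std <- fit_gamm(ds, habitat_spec("fpt", "sst_C"))
  expect_equal(fitted(raw$model), fitted(std$model), tolerance = 1e-6)
})

test_that("AIC improves when the true generating term enters the model", {
  d <- gen_daily_table(5)
  null <- fit_gamm(d, habitat_spec("fpt"))
  sst <- fit_gamm(d, habitat_spec("fpt", "sst_C"))
  expect_lt(sst$aic, null$aic)
})

test_that("spec enumeration covers the power set of smooth terms", {
  specs <- enumerate_habitat_specs("fpt")
  sigs <- sort(sapply(specs, function(s) paste(sort(s$smooths), collapse = "+")))
  expect_equal(sigs, c("", "bathymetry_m", "bathymetry_m+sst_C", "sst_C"))
})

test_that("model selection applies the AIC-parsimony rule", {
  mk <- function(aic, npar, terms) structure(
    list(aic = aic, n_params = npar, spec = list(smooths = terms)),
    class = "gamm_fit")
  # {100, 101.5 with one fewer parameter, 104} -> the 101.5 model
  fits <- list(mk(100, 3, c("a", "b")), mk(101.5, 2, "a"), mk(104, 2, "b"))
  expect_equal(select_model(fits)$aic, 101.5)
  # a single fit selects itself
  expect_equal(select_model(fits[1])$aic, 100)
  # brute-force rule application on random AIC sets
  set.seed(24)
  for (rep in 1:20) {
    aics <- round(runif(5, 100, 110), 2)
    npars <- sample(1:4, 5, replace = TRUE)
    fits <- lapply(1:5, function(i) mk(aics[i], npars[i], letters[i]))
    got <- select_model(fits)
    cand <- which(aics - min(aics) < 2)
    best <- cand[order(npars[cand], aics[cand], letters[cand])][1]
    expect_equal(got$aic, aics[best])
  }
})
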