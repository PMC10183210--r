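# shared simulated model frames ------------------------------------------

sim_count_frame <- function(seed, n_group = 12, per_group = 4,
                            beta_pop = -0.8, sd_group = 0.4,
                            family = c("poisson", "nbinom1"), alpha = 1) {
  family <- match.arg(family)
  set.seed(seed)
  g <- rep(seq_len(n_group), each = per_group)
  b <- rnorm(n_group, 0, sd_group)
  pop <- factor(rep(c("NRKW", "SRKW"), length.out = n_group * per_group))
  dur <- runif(n_group * per_group, 1, 8)
  eta <- 1 + beta_pop * (pop == "SRKW") + b[g] + log(dur)
  mu <- exp(eta)
  y <- if (family == "poisson") rpois(length(mu), mu)
       else rnbinom(length(mu), mu = mu, size = mu / alpha)  # var mu(1+alpha)
  data.frame(y = y, population = pop, duration_h = dur,
             week_year = factor(g))
}

test_that("boundary proportions are compressed, interior left alone", {
  expect_equal(transform_beta_response(0, 51), 0.5 / 51)
  expect_equal(transform_beta_response(1, 51), 50.5 / 51)
  expect_equal(transform_beta_response(0.3, 51), 0.3)
  expect_equal(transform_beta_response(c(0, 0.25, 1), 10),
               c(0.05, 0.25, 0.95))
  expect_error(transform_beta_response(0.5, 1), ">= 2")
  expect_error(transform_beta_response(1.2, 10), "0, 1|\\[0, 1\\]")
})

test_that("model specifications enforce their structural rules", {
  expect_error(model_spec("y", "beta", "population", offset = "log(d)"),
               "count")
  expect_error(model_spec("y", "poisson", "population",
                          random = c("a", "b", "c")), "at most two")
  expect_error(model_spec("y", "poisson", "population",
                          dispersion = "sex"), "beta")
  sp <- model_spec("y", "poisson", c("population", "sex"),
                   random = "week_year", offset = "log(duration_h)")
  expect_true(inherits(sp$formula, "formula"))
})

test_that("mixed fits collapse to fixed-effects fits at zero variance", {
  # data generated with no group effect: the lme4 variance estimate hits
  # the boundary for some realizations; on those, coefficients must match
  # the plain Poisson regression to numerical precision
  hits <- 0
  for (seed in 1:6) {
    d <- sim_count_frame(seed, sd_group = 0)
    sp <- model_spec("y", "poisson", "population", random = "week_year",
                     offset = "log(duration_h)")
    f_mix <- fit_glmm(sp, d, engine = "lme4", nAGQ = 9)
    if (f_mix$varcomp[["week_year"]] < 1e-10) {
      hits <- hits + 1
      f_glm <- glm(y ~ population + offset(log(duration_h)), poisson, d)
      expect_lt(max(abs(f_mix$coefficients$estimate - coef(f_glm))), 1e-6)
    }
  }
  expect_gt(hits, 0)
})

test_that("quadrature log-likelihood is stable between 9 and 15 nodes", {
  d <- demography_table(dtag_deployments(), "adult_females")
  sp <- model_spec("n_capture_dives", "poisson", c("population", "calf"),
                   random = "week_year", offset = "log(duration_h)")
  ll <- vapply(c(9, 15), function(q)
    fit_glmm(sp, d, engine = "lme4", nAGQ = q)$logLik, numeric(1))
  expect_lt(abs(diff(ll)), 1e-4)
})

test_that("nbinom1 reduces to Poisson as the dispersion vanishes", {
  d <- sim_count_frame(42, family = "poisson")
  sp_p <- model_spec("y", "poisson", "population", random = "week_year",
                     offset = "log(duration_h)")
  sp_nb <- model_spec("y", "nbinom1", "population", random = "week_year",
                      offset = "log(duration_h)")
  f_p <- fit_glmm(sp_p, d, REML = FALSE)
  # the dispersion estimate sits on its boundary: the optimizer warns about
  # the Hessian there, which is exactly the regime under test
  f_nb <- suppressWarnings(fit_glmm(sp_nb, d, REML = FALSE))
  expect_lt(max(abs(f_p$coefficients$estimate - f_nb$coefficients$estimate)),
            5e-3)
})

test_that("beta models accept a dispersion covariate", {
  set.seed(7)
  n <- 120
  pop <- factor(rep(c("NRKW", "SRKW"), each = n / 2))
  sex <- factor(rep(c("F", "M"), n / 2))
  mu <- plogis(-1 + 0.8 * (pop == "SRKW"))
  phi <- ifelse(sex == "M", 30, 8)
  y <- rbeta(n, mu * phi, (1 - mu) * phi)
  d <- data.frame(y = transform_beta_response(y, n), population = pop,
                  sex = sex, week_year = factor(rep(1:10, length.out = n)))
  sp <- model_spec("y", "beta", "population", random = "week_year",
                   dispersion = "sex")
  f <- fit_glmm(sp, d, REML = FALSE)
  expect_true(f$converged)
  expect_equal(coef_of(f, "population")[[1]], 0.8, tolerance = 0.35)
})

test_that("random-structure selection applies the delta-2 parsimony rule", {
  # with no true group effect the mixed model matches the fixed-effects
  # model's likelihood but spends one more parameter (delta AIC ~ 2): the
  # rule must pick the simpler fixed-effects candidate
  d <- sim_count_frame(3, sd_group = 0)
  cands <- list(
    model_spec("y", "poisson", "population", random = "week_year",
               offset = "log(duration_h)"),
    model_spec("y", "poisson", "population", offset = "log(duration_h)"))
  sel <- select_random_structure(cands, d, REML = FALSE)
  expect_length(sel$random, 0)
  expect_s3_class(attr(sel, "aic_table"), "data.frame")

  # a strong group effect makes the mixed candidate win outright
  d2 <- sim_count_frame(4, sd_group = 1.2)
  sel2 <- select_random_structure(cands, d2, REML = FALSE)
  expect_equal(sel2$random, "week_year")

  # single candidate: returned as-is
  expect_identical(select_random_structure(cands[1], d, REML = FALSE)$random,
                   "week_year")
})

test_that("backward deletion respects marginality and the alpha rule", {
  set.seed(12)
  n <- 160
  pop <- factor(rep(c("NRKW", "SRKW"), each = n / 2))
  sex <- factor(rep(c("F", "M"), n / 2))
  wk <- factor(rep(1:8, length.out = n))

  # null interaction, strong main effect of population
  y <- rpois(n, exp(1 + 1 * (pop == "SRKW")))
  d <- data.frame(y = y, population = pop, sex = sex, week_year = wk)
  full <- model_spec("y", "poisson",
                     c("population", "sex", "population:sex"),
                     random = "week_year")
  red <- drop_terms_lrt(full, d)
  expect_false("population:sex" %in% red$fixed)
  expect_true("population" %in% red$fixed)
  tr <- attr(red, "deletion_trace")
  # only the interaction is droppable while it is present (marginality)
  expect_equal(tr$term[tr$step == 1], "population:sex")

  # strong interaction: nothing is dropped, main effects stay protected
  y2 <- rpois(n, exp(0.5 + 1.5 * (pop == "SRKW") * (sex == "M")))
  d2 <- data.frame(y = y2, population = pop, sex = sex, week_year = wk)
  red2 <- drop_terms_lrt(full, d2)
  expect_setequal(red2$fixed, c("population", "sex", "population:sex"))
})

test_that("pairwise contrasts enumerate level pairs with adjustment", {
  d <- dtag_deployments()
  d2 <- d[d$sex != "unknown", ]
  d2$sex <- droplevels(d2$sex)
  sp <- model_spec("n_capture_dives", "poisson",
                   c("population", "sex", "population:sex"),
                   random = "week_year", offset = "log(duration_h)")
  f <- fit_glmm(sp, d2, REML = FALSE)
  # four population x sex cells -> choose(4, 2) contrasts
  pc <- pairwise_contrasts(f, "population:sex")
  expect_equal(nrow(pc), 6)
  expect_true(all(pc$p_adjusted >= 0 & pc$p_adjusted <= 1))
  # two-level factor -> a single contrast
  pc2 <- pairwise_contrasts(f, "population")
  expect_equal(nrow(pc2), 1)
  expect_error(pairwise_contrasts(f, "duration_h"), "not in the model|factor")
})

test_that("the overdispersion check calibrates against its own model", {
  d <- sim_count_frame(21, sd_group = 0.3)
  sp <- model_spec("y", "poisson", "population", random = "week_year",
                   offset = "log(duration_h)")
  f <- fit_glmm(sp, d, REML = FALSE)
  ok <- overdispersion_check(f, n_sim = 200, seed = 1)
  expect_equal(ok$ratio, 1, tolerance = 0.35)
  expect_gt(ok$p, 0.05)

  # strongly overdispersed data fitted as Poisson: large ratio, small p
  d_od <- sim_count_frame(22, family = "nbinom1", alpha = 4, sd_group = 0)
  f_od <- fit_glmm(sp, d_od, REML = FALSE)
  bad <- overdispersion_check(f_od, n_sim = 200, seed = 1)
  expect_gt(bad$ratio, 1.3)
  expect_lt(bad$p, 0.05)

  expect_error(overdispersion_check(f, n_sim = 0), "n_sim")
  sp_b <- model_spec("prop", "beta", "population")
  expect_error(overdispersion_check(structure(list(spec = sp_b),
                                              class = "forage_fit")),
               "count")
})

test_that("non-convergence is flagged, never silently repaired", {
  # two-level factor with a single observation per level of a random effect
  # that is confounded with the response scale: force a hard problem
  d <- data.frame(y = c(0, 0, 0, 0), population = factor(c("A", "B", "A", "B")),
                  week_year = factor(1:4), duration_h = 1)
  sp <- model_spec("y", "poisson", "population", random = "week_year",
                   offset = "log(duration_h)")
  f <- tryCatch(suppressWarnings(fit_glmm(sp, d, REML = FALSE)),
                error = function(e) NULL)
  if (!is.null(f)) expect_type(f$converged, "logical")
})
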