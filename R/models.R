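#' Specify a mixed model for a foraging metric
#'
#' Builds a model specification in the family set used for foraging
#' comparisons: Poisson and linear-mean-variance negative binomial
#' (`nbinom1`, variance `mu * (1 + alpha)`) counts with log link, beta
#' proportions with logit link (optionally with a log-linear dispersion
#' covariate), and Gaussian responses. Counts may carry an offset (entered
#' in the linear predictor with coefficient 1, e.g. `log(duration_h)` or
#' `sqrt(searching_h)`); up to two random intercepts are supported.
#'
#' @param response Response variable name.
#' @param family One of `"poisson"`, `"nbinom1"`, `"beta"`, `"gaussian"`.
#' @param fixed Character vector of fixed-effect terms, e.g.
#'   `c("population", "sex", "population:sex")`.
#' @param random Character vector (length 0--2) of random-intercept factors,
#'   e.g. `"week_year"`.
#' @param offset Offset expression as a string (count families only), or
#'   `NULL`.
#' @param dispersion Dispersion covariate name (beta family only), or
#'   `NULL`.
#' @return List of class `model_spec` with a ready-to-fit `formula`.
#' @seealso [fit_glmm()]
#' @export
model_spec <- function(response, family = c("poisson", "nbinom1", "beta",
                                            "gaussian"),
                       fixed, random = character(), offset = NULL,
                       dispersion = NULL) {
  family <- match.arg(family)
  if (length(random) > 2L) stop("at most two random intercepts are supported")
  if (!is.null(offset) && !family %in% c("poisson", "nbinom1"))
    stop("offsets are only used with count families")
  if (!is.null(dispersion) && family != "beta")
    stop("a dispersion covariate is only used with the beta family")
  rhs <- paste(fixed, collapse = " + ")
  if (!is.null(offset)) rhs <- paste0(rhs, " + offset(", offset, ")")
  if (length(random) > 0L)
    rhs <- paste(rhs, paste0("(1 | ", random, ")", collapse = " + "),
                 sep = " + ")
  structure(list(
    response = response, family = family, fixed = fixed, random = random,
    offset = offset, dispersion = dispersion,
    formula = stats::as.formula(paste(response, "~", rhs))
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec [", x$family, "]: ", deparse(x$formula), "\n", sep = "")
  if (!is.null(x$dispersion))
    cat("  dispersion ~", x$dispersion, "\n")
  invisible(x)
}

#' Transform boundary proportions for beta regression
#'
#' The beta likelihood is undefined at exactly 0 or 1; boundary values are
#' shrunk toward the interior by `(y * (n - 1) + 0.5) / n` (the standard
#' sample-size-weighted compression), leaving interior values untouched.
#'
#' @param y Proportions in [0, 1].
#' @param n Number of observations behind the transform; must be >= 2.
#' @return Proportions in (0, 1).
#' @examples
#' transform_beta_response(c(0, 0.3, 1), n = 51)
#' @export
transform_beta_response <- function(y, n) {
  if (n < 2) stop("n must be >= 2")
  if (any(y < 0 | y > 1, na.rm = TRUE)) stop("y must lie in [0, 1]")
  boundary <- !is.na(y) & (y == 0 | y == 1)
  y[boundary] <- (y[boundary] * (n - 1) + 0.5) / n
  y
}

fit_engine_for <- function(spec, engine) {
  if (engine != "auto") return(engine)
  switch(spec$family,
         gaussian = "lme4",
         poisson = "glmmTMB",
         nbinom1 = "glmmTMB",
         beta = "glmmTMB")
}

#' Fit a mixed model for a foraging metric
#'
#' Fits a [model_spec()] by maximum likelihood (or REML). Two engines are
#' available:
#' \describe{
#'   \item{`glmmTMB`}{Laplace approximation via TMB; supports all four
#'     families, REML, and log-linear dispersion covariates for beta models.
#'     This is the default for non-Gaussian families and matches the
#'     estimates of the original analyses of this data type.}
#'   \item{`lme4`}{`lmer` for Gaussian responses (REML by default, up to two
#'     crossed random intercepts) and `glmer` with adaptive Gauss--Hermite
#'     quadrature (`nAGQ` nodes) for Poisson models with a single random
#'     intercept.}
#' }
#' Non-convergence is flagged on the result, never silently replaced by a
#' different model.
#'
#' @param spec A [model_spec()].
#' @param data Model frame containing all variables.
#' @param engine `"auto"` (family-dependent default), `"glmmTMB"`, or
#'   `"lme4"`.
#' @param REML Use restricted maximum likelihood. Default `TRUE` for final
#'   fits; likelihood-ratio comparisons refit with `REML = FALSE`.
#' @param nAGQ Quadrature nodes for the lme4 Poisson path. Default 9.
#' @return List of class `forage_fit`: `spec`, `model` (the fitted object),
#'   `engine`, `coefficients` (term, estimate, se, statistic, p),
#'   `varcomp` (random-intercept variances), `dispersion`, `logLik`, `AIC`,
#'   `n`, `n_parameters`, `converged`.
#' @export
fit_glmm <- function(spec, data, engine = c("auto", "glmmTMB", "lme4"),
                     REML = TRUE, nAGQ = 9) {
  stopifnot(inherits(spec, "model_spec"))
  engine <- fit_engine_for(spec, match.arg(engine))
  vars <- all.vars(spec$formula)
  if (!all(vars %in% names(data)))
    stop("data lacks variable(s): ",
         paste(setdiff(vars, names(data)), collapse = ", "))
  data <- data[stats::complete.cases(data[vars]), , drop = FALSE]
  for (f in spec$fixed) {
    v <- strsplit(f, ":")[[1]]
    for (vv in v)
      if (is.factor(data[[vv]]) && nlevels(droplevels(data[[vv]])) < 2L)
        stop("factor '", vv, "' has fewer than 2 levels in the data")
  }
  if (spec$family == "beta" &&
      any(data[[spec$response]] <= 0 | data[[spec$response]] >= 1))
    stop("beta response must lie in (0, 1); see transform_beta_response()")

  has_random <- length(spec$random) > 0L
  if (engine == "lme4") {
    if (spec$family %in% c("nbinom1", "beta"))
      stop("family '", spec$family, "' requires the glmmTMB engine")
    if (spec$family == "gaussian") {
      model <- if (has_random)
        lme4::lmer(spec$formula, data = data, REML = REML)
      else stats::lm(spec$formula, data = data)
    } else {
      if (length(spec$random) > 1L)
        stop("adaptive quadrature supports a single random intercept")
      model <- if (has_random)
        lme4::glmer(spec$formula, data = data, family = stats::poisson(),
                    nAGQ = nAGQ)
      else stats::glm(spec$formula, data = data, family = stats::poisson())
    }
  } else {
    fam <- switch(spec$family,
                  poisson = stats::poisson(),
                  nbinom1 = glmmTMB::nbinom1(),
                  beta = glmmTMB::beta_family(),
                  gaussian = stats::gaussian())
    dispformula <- if (is.null(spec$dispersion)) ~1
                   else stats::as.formula(paste("~", spec$dispersion))
    model <- glmmTMB::glmmTMB(spec$formula, data = data, family = fam,
                              dispformula = dispformula, REML = REML)
  }
  new_forage_fit(spec, model, engine, nrow(data))
}

new_forage_fit <- function(spec, model, engine, n) {
  if (inherits(model, "glmmTMB")) {
    sm <- summary(model)$coefficients$cond
    vc <- glmmTMB::VarCorr(model)$cond
    varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
    disp <- tryCatch(glmmTMB::sigma(model), error = function(e) NA_real_)
    converged <- isTRUE(model$fit$convergence == 0) &&
      isTRUE(model$sdr$pdHess)
  } else if (inherits(model, "merMod")) {
    sm <- summary(model)$coefficients
    vc <- lme4::VarCorr(model)
    varcomp <- vapply(vc, function(v) as.numeric(v[1, 1]), numeric(1))
    disp <- stats::sigma(model)
    converged <- length(model@optinfo$conv$lme4$messages) == 0L
  } else {  # lm / glm
    sm <- summary(model)$coefficients
    varcomp <- numeric()
    disp <- stats::sigma(model)
    converged <- TRUE
  }
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1], se = sm[, 2],
                      statistic = sm[, 3],
                      p = if (ncol(sm) >= 4) sm[, 4] else NA_real_,
                      row.names = NULL, stringsAsFactors = FALSE)
  ll <- stats::logLik(model)
  structure(list(
    spec = spec, model = model, engine = engine,
    coefficients = coefs, varcomp = varcomp, dispersion = disp,
    logLik = as.numeric(ll), AIC = stats::AIC(model), n = n,
    n_parameters = attr(ll, "df"), converged = converged
  ), class = "forage_fit")
}

#' @export
print.forage_fit <- function(x, ...) {
  cat("forage_fit [", x$spec$family, ", ", x$engine, "]: ",
      deparse(x$spec$formula), "\n", sep = "")
  cat(sprintf("  n = %d, logLik = %.2f, AIC = %.2f%s\n", x$n, x$logLik, x$AIC,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(x$coefficients, digits = 4)
  if (length(x$varcomp) > 0) {
    cat("  random-intercept variances:\n")
    print(x$varcomp, digits = 4)
  }
  invisible(x)
}

#' Coefficient of a fitted term
#'
#' Convenience accessor for a single fixed-effect estimate by (partial)
#' term name.
#'
#' @param fit A `forage_fit`.
#' @param term Term name (exact match, or unique prefix of the coefficient
#'   name such as `"population"`).
#' @return Named numeric estimate.
#' @export
coef_of <- function(fit, term) {
  co <- fit$coefficients
  i <- which(co$term == term)
  if (length(i) == 0L) i <- grep(paste0("^", term), co$term)
  if (length(i) != 1L)
    stop("term '", term, "' does not identify a unique coefficient")
  stats::setNames(co$estimate[i], co$term[i])
}

#' Select the random structure by AIC
#'
#' Fits candidate specifications sharing the same fixed structure and
#' selects among those within 2 AIC units of the minimum, preferring the
#' model with the fewest estimated parameters; remaining ties go to the
#' fewest random factors, then to candidate order. Candidates that fail to
#' converge are excluded with a warning.
#'
#' @param candidates List of [model_spec()]s with identical fixed effects.
#' @param data Model frame.
#' @param ... Passed to [fit_glmm()].
#' @return The selected `model_spec`, with the AIC comparison attached as
#'   attribute `"aic_table"`.
#' @export
select_random_structure <- function(candidates, data, ...) {
  fits <- lapply(candidates, function(sp)
    tryCatch(fit_glmm(sp, data, ...), error = function(e) NULL))
  ok <- vapply(fits, function(f) !is.null(f) && f$converged, logical(1))
  if (any(!ok))
    warning(sum(!ok), " candidate(s) excluded for non-convergence")
  if (!any(ok)) stop("no candidate converged")
  aic <- vapply(fits[ok], `[[`, numeric(1), "AIC")
  k <- vapply(fits[ok], `[[`, numeric(1), "n_parameters")
  nr <- vapply(candidates[ok], function(s) length(s$random), numeric(1))
  idx_ok <- which(ok)
  in_band <- aic - min(aic) <= 2
  ord <- order(!in_band, k, nr, seq_along(aic))
  chosen <- idx_ok[ord[1]]
  out <- candidates[[chosen]]
  attr(out, "aic_table") <- data.frame(
    formula = vapply(candidates[ok], function(s) deparse(s$formula),
                     character(1)),
    AIC = aic, delta = aic - min(aic), n_parameters = k,
    n_random = nr, stringsAsFactors = FALSE)
  out
}

droppable_terms <- function(fixed) {
  if (length(fixed) == 0L) return(character())
  f <- stats::reformulate(fixed)
  stats::drop.scope(f)
}

#' Backward term deletion by likelihood-ratio tests
#'
#' Recursive single-term deletion: repeatedly refits the model without each
#' currently droppable fixed term (interactions are dropped before the main
#' effects they contain -- the marginality principle), removes the term with
#' the largest likelihood-ratio p value at or above `alpha`, and stops when
#' every remaining droppable term tests significant. All comparisons refit
#' by maximum likelihood (`REML = FALSE`), as required for fixed-effect
#' likelihood-ratio tests.
#'
#' @param spec Full [model_spec()].
#' @param data Model frame.
#' @param alpha Retention threshold. Default 0.05.
#' @param ... Passed to [fit_glmm()].
#' @return The reduced `model_spec`, with a `"deletion_trace"` attribute
#'   recording each tested term, its LRT statistic, df, p value, and whether
#'   it was dropped.
#' @export
drop_terms_lrt <- function(spec, data, alpha = 0.05, ...) {
  stopifnot(inherits(spec, "model_spec"))
  trace <- data.frame(step = integer(), term = character(), lrt = numeric(),
                      df = numeric(), p = numeric(), dropped = logical(),
                      stringsAsFactors = FALSE)
  fixed <- spec$fixed
  step <- 0L
  repeat {
    step <- step + 1L
    full_spec <- model_spec(spec$response, spec$family, fixed, spec$random,
                            spec$offset, spec$dispersion)
    full <- fit_glmm(full_spec, data, REML = FALSE, ...)
    cand <- droppable_terms(fixed)
    if (length(cand) == 0L) break
    res <- lapply(cand, function(tm) {
      red <- model_spec(spec$response, spec$family, setdiff(fixed, tm),
                        spec$random, spec$offset, spec$dispersion)
      rf <- fit_glmm(red, data, REML = FALSE, ...)
      lrt <- 2 * (full$logLik - rf$logLik)
      df <- full$n_parameters - rf$n_parameters
      p <- stats::pchisq(max(lrt, 0), df = max(df, 1), lower.tail = FALSE)
      c(lrt = lrt, df = df, p = p)
    })
    p <- vapply(res, `[[`, numeric(1), "p")
    worst <- which.max(p)
    drop_it <- p[worst] >= alpha
    trace <- rbind(trace, data.frame(
      step = step, term = cand,
      lrt = vapply(res, `[[`, numeric(1), "lrt"),
      df = vapply(res, `[[`, numeric(1), "df"), p = p,
      dropped = drop_it & seq_along(cand) == worst))
    if (!drop_it) break
    fixed <- setdiff(fixed, cand[worst])
    if (length(fixed) == 0L) break
  }
  out <- model_spec(spec$response, spec$family, fixed, spec$random,
                    spec$offset, spec$dispersion)
  attr(out, "deletion_trace") <- trace
  out
}

#' Pairwise contrasts of factor levels with familywise adjustment
#'
#' All pairwise differences of estimated marginal means on the link scale
#' for the levels of a model factor (or combination such as
#' `"population:sex"`), with single-step multivariate-t ("Tukey")
#' familywise adjustment of p values.
#'
#' @param fit A `forage_fit`.
#' @param factor Factor name(s) in the model; combine with `:` for cell
#'   means of an interaction.
#' @return data.frame with `contrast`, `estimate`, `se`, `p_adjusted`.
#' @export
pairwise_contrasts <- function(fit, factor) {
  stopifnot(inherits(fit, "forage_fit"))
  facs <- strsplit(factor, ":")[[1]]
  mf <- stats::model.frame(fit$model)
  for (f in facs) {
    if (!f %in% names(mf)) stop("factor '", f, "' is not in the model")
    if (nlevels(droplevels(as.factor(mf[[f]]))) < 2L)
      stop("factor '", f, "' has a single level")
  }
  emm <- emmeans::emmeans(fit$model,
                          specs = stats::as.formula(paste(
                            "~", paste(facs, collapse = "*"))))
  pr <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  data.frame(contrast = pr$contrast, estimate = pr$estimate, se = pr$SE,
             p_adjusted = pr$p.value, stringsAsFactors = FALSE)
}

#' Simulation-based overdispersion check for count models
#'
#' Compares the observed Pearson dispersion (sum of squared Pearson
#' residuals over residual degrees of freedom) to its distribution under the
#' fitted model, by simulating `n_sim` response vectors from the fitted
#' conditional distribution (the fitted means given the estimated random
#' effects, with the family's mean-variance law) and recomputing the
#' statistic -- a plug-in parametric bootstrap. The reported ratio is
#' observed dispersion over the simulated mean; the p value is two-sided
#' with the usual +1 correction.
#'
#' @param fit A `forage_fit` with a count family.
#' @param n_sim Number of simulated response vectors; must be >= 1.
#'   Default 250.
#' @param seed Optional RNG seed for reproducibility.
#' @return List with `ratio`, `p`, `observed`, and the vector `simulated`.
#' @export
overdispersion_check <- function(fit, n_sim = 250, seed = NULL) {
  stopifnot(inherits(fit, "forage_fit"))
  if (!fit$spec$family %in% c("poisson", "nbinom1"))
    stop("overdispersion check applies to count families")
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  model <- fit$model
  mu <- stats::fitted(model)
  y <- stats::model.response(stats::model.frame(model))
  vfun <- if (fit$spec$family == "poisson") function(m) m
          else {
            alpha <- fit$dispersion  # nbinom1: variance = mu * (1 + alpha)
            function(m) m * (1 + alpha)
          }
  df_resid <- length(y) - fit$n_parameters
  pearson <- function(yy) sum((yy - mu)^2 / vfun(mu)) / max(df_resid, 1)
  obs <- pearson(y)
  draw <- if (fit$spec$family == "poisson")
    function() stats::rpois(length(mu), mu)
  else {
    alpha <- fit$dispersion
    # nbinom1: variance mu * (1 + alpha) corresponds to size = mu / alpha
    function() stats::rnbinom(length(mu), mu = mu, size = mu / alpha)
  }
  stat <- vapply(seq_len(n_sim), function(i) pearson(draw()), numeric(1))
  p_hi <- (sum(stat >= obs) + 1) / (n_sim + 1)
  p_lo <- (sum(stat <= obs) + 1) / (n_sim + 1)
  list(ratio = obs / mean(stat), p = min(1, 2 * min(p_hi, p_lo)),
       observed = obs, simulated = stat)
}

#' Demographic model frames for count models
#'
#' Prepares the adult-female (calf presence) or adult-male (living mother)
#' subsets for the demographic count models: filters to adults of the
#' relevant sex with known demographic status, and encodes the demographic
#' predictor as a two-level factor (`no`/`yes` for calf presence,
#' `dead`/`alive` for a living mother).
#'
#' @param records A `deployment_table`.
#' @param which `"adult_females"` or `"adult_males"`.
#' @return data.frame with `deployment_id`, `population`, `week_year`,
#'   `duration_h`, `n_capture_dives`, and `calf` or `mother`.
#' @export
demography_table <- function(records,
                             which = c("adult_females", "adult_males")) {
  which <- match.arg(which)
  if (which == "adult_females") {
    d <- records[records$adult & records$sex == "F" &
                   records$calf_status != "not_applicable", , drop = FALSE]
    d$calf <- factor(ifelse(d$calf_status == "with_calf", "yes", "no"),
                     levels = c("no", "yes"))
  } else {
    d <- records[records$adult & records$sex == "M" &
                   records$mother_status != "not_applicable", , drop = FALSE]
    d$mother <- factor(ifelse(d$mother_status == "mother_alive", "alive",
                              "dead"),
                       levels = c("dead", "alive"))
  }
  d$population <- droplevels(d$population)
  rownames(d) <- NULL
  d
}
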