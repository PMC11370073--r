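# Trajectory models: restricted-cubic-spline mixed models for day-level
# movement behaviours (linear, REML) and child-level guideline adherence
# (logistic, Laplace), with age-by-sex interaction, covariate adjustment,
# random child intercepts, marginal means on an age grid, and Wald joint
# tests; plus small study-design utilities.

AGE_BASIS_COLS <- c(".age_lin", ".age_nl1", ".age_nl2")

prep_model_frame <- function(data, outcome, age, sex, id, covariates, spec) {
  needed <- c(outcome, age, sex, id, covariates)
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    abort_arg(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  d <- as.data.frame(data[needed])
  if (anyNA(d)) {
    n0 <- nrow(d)
    d <- d[stats::complete.cases(d), , drop = FALSE]
    message(sprintf("dropped %d rows with missing values", n0 - nrow(d)))
  }
  if (is.null(spec)) spec <- place_knots(d[[age]])
  B <- rcs_basis(d[[age]], spec)
  nb <- ncol(B)
  basis_cols <- c(".age_lin", paste0(".age_nl", seq_len(nb - 1)))
  for (j in seq_len(nb)) d[[basis_cols[j]]] <- B[, j]
  if (!is.factor(d[[sex]])) d[[sex]] <- factor(d[[sex]], levels = c("female", "male"))
  for (cv in covariates) {
    if (is.logical(d[[cv]]) || is.character(d[[cv]])) d[[cv]] <- factor(d[[cv]])
  }
  list(data = d, spec = spec, basis_cols = basis_cols)
}

build_fixed_rhs <- function(basis_cols, sex, covariates) {
  rhs <- paste0(
    "(", paste(basis_cols, collapse = " + "), ") * ", sex,
    if (length(covariates) > 0) paste0(" + ", paste(covariates, collapse = " + ")) else ""
  )
  rhs
}

new_trajectory_fit <- function(model, family, outcome, age, sex, id, covariates,
                               spec, basis_cols, fixed_rhs, frame) {
  cov_reference <- purrr::map(setNames(covariates, covariates), function(cv) {
    v <- frame[[cv]]
    if (is.numeric(v)) mean(v) else factor(levels(v)[1], levels = levels(v))
  })
  xlev <- purrr::compact(purrr::map(
    setNames(c(sex, covariates), c(sex, covariates)),
    function(cl) if (is.factor(frame[[cl]])) levels(frame[[cl]]) else NULL
  ))
  conv <- is.null(model@optinfo$conv$lme4$messages) ||
    !any(grepl("failed to converge", model@optinfo$conv$lme4$messages))
  structure(
    list(
      model = model, family = family, outcome = outcome,
      age_col = age, sex_col = sex, id_col = id, covariates = covariates,
      spec = spec, basis_cols = basis_cols, fixed_rhs = fixed_rhs,
      cov_reference = cov_reference, xlevels = xlev,
      cov_rows = unique(frame[c(sex, covariates)]),
      cov_rows_full = frame[c(sex, covariates)],
      age_range = range(frame[[age]]),
      converged = conv,
      degenerate = FALSE
    ),
    class = "trajectory_fit"
  )
}

#' Fit a linear spline mixed model for a movement behaviour
#'
#' Fits, by REML, the model
#' `outcome ~ rcs(age) * sex + covariates + (1 | child)` where `rcs(age)` is
#' the restricted-cubic-spline basis of [rcs_basis()] (four knots by
#' default, placed by [place_knots()] on the observed ages).
#'
#' @param data Day-level data (e.g. `simulate_cohort()$days`).
#' @param outcome Name of the minutes-per-day outcome column.
#' @param age,sex,id Column names (defaults `age_years`, `sex`, `child_id`).
#' @param covariates Character vector of adjustment covariate columns
#'   (e.g. maternal work status, dwelling type, yard size, wear time,
#'   season, COVID-period flag). Default none.
#' @param spec An [rcs_spec()]; `NULL` places knots from the data.
#'
#' @return Object of class `trajectory_fit`.
#' @export
fit_trajectory_lmm <- function(data, outcome, age = "age_years", sex = "sex",
                               id = "child_id", covariates = character(),
                               spec = NULL) {
  pf <- prep_model_frame(data, outcome, age, sex, id, covariates, spec)
  rhs <- build_fixed_rhs(pf$basis_cols, sex, covariates)
  form <- formula(paste0(outcome, " ~ ", rhs, " + (1 | ", id, ")"))
  model <- lme4::lmer(form, data = pf$data, REML = TRUE)
  new_trajectory_fit(
    model, "gaussian", outcome, age, sex, id, covariates,
    pf$spec, pf$basis_cols, rhs, pf$data
  )
}

#' Fit a logistic spline mixed model for guideline adherence
#'
#' As [fit_trajectory_lmm()] but with a binary outcome, logit link and the
#' Laplace approximation (`lme4::glmer`). A degenerate outcome (all
#' children meeting, or none — complete separation on the intercept) is
#' flagged rather than fitted: the returned object has `degenerate = TRUE`
#' and no finite estimates are claimed.
#'
#' @inheritParams fit_trajectory_lmm
#' @return Object of class `trajectory_fit` (log-odds scale estimates).
#' @export
fit_trajectory_glmm <- function(data, outcome, age = "age_years", sex = "sex",
                                id = "child_id", covariates = character(),
                                spec = NULL) {
  y <- data[[outcome]]
  if (length(unique(y[!is.na(y)])) < 2) {
    return(structure(
      list(
        model = NULL, family = "binomial", outcome = outcome,
        degenerate = TRUE, converged = FALSE,
        message = "degenerate outcome: no variation in adherence (separation)"
      ),
      class = "trajectory_fit"
    ))
  }
  pf <- prep_model_frame(data, outcome, age, sex, id, covariates, spec)
  rhs <- build_fixed_rhs(pf$basis_cols, sex, covariates)
  form <- formula(paste0(outcome, " ~ ", rhs, " + (1 | ", id, ")"))
  model <- lme4::glmer(form,
    data = pf$data, family = stats::binomial(), nAGQ = 1,
    control = lme4::glmerControl(optimizer = "bobyqa", optCtrl = list(maxfun = 1e5))
  )
  new_trajectory_fit(
    model, "binomial", outcome, age, sex, id, covariates,
    pf$spec, pf$basis_cols, rhs, pf$data
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<trajectory_fit>", x$outcome, "-", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<trajectory_fit> %s (%s), knots at %s, %s\n",
    x$outcome, x$family, paste(signif(x$spec$knots, 3), collapse = ", "),
    if (x$converged) "converged" else "NOT converged"
  ))
  print(tidy.trajectory_fit(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trajectory_fit <- function(x, ...) {
  if (x$degenerate) abort_arg("degenerate fit has no estimates.")
  b <- lme4::fixef(x$model)
  se <- sqrt(diag(as.matrix(vcov(x$model))))
  z <- b / se
  tibble::tibble(
    term = names(b), estimate = unname(b), std.error = unname(se),
    statistic = unname(z), p.value = unname(2 * pnorm(-abs(z)))
  )
}

#' @exportS3Method generics::glance
glance.trajectory_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(
      nobs = NA_integer_, n_children = NA_integer_, converged = FALSE,
      degenerate = TRUE
    ))
  }
  vc <- as.data.frame(lme4::VarCorr(x$model))
  ri <- vc$sdcor[vc$grp == x$id_col][1]
  tibble::tibble(
    nobs = stats::nobs(x$model),
    n_children = lme4::ngrps(x$model)[[x$id_col]],
    random_intercept_sd = ri,
    sigma = if (x$family == "gaussian") stats::sigma(x$model) else NA_real_,
    logLik = as.numeric(stats::logLik(x$model)),
    converged = x$converged,
    degenerate = FALSE
  )
}

# Fixed-effects design matrix for prediction rows.
fixed_design <- function(fit, newdata) {
  B <- rcs_basis(newdata[[fit$age_col]], fit$spec)
  for (j in seq_along(fit$basis_cols)) newdata[[fit$basis_cols[j]]] <- B[, j]
  model.matrix(
    formula(paste0("~ ", fit$fixed_rhs)),
    data = newdata, xlev = fit$xlevels
  )
}

#' Marginal means over an age-by-sex grid
#'
#' Model predictions at each (age, sex) grid point with the remaining
#' covariates held fixed. Under `policy = "reference"` continuous
#' covariates sit at their sample mean and categorical covariates at their
#' reference level; under `policy = "population"` predictions are averaged
#' over the observed covariate rows (population-averaged on the linear
#' predictor). Confidence intervals are delta-method normal-approximation
#' 95% intervals; logistic fits are back-transformed to proportions.
#'
#' @param fit A [fit_trajectory_lmm()] / [fit_trajectory_glmm()] result.
#' @param ages Age grid in years (default `2:7`). A warning is attached
#'   when the grid extends beyond the ages the model was fitted to.
#' @param sexes Sex levels (default those of the fit).
#' @param policy Covariate policy, `"reference"` (default) or
#'   `"population"`.
#'
#' @return Tibble of class `marginal_means`: `outcome`, `sex`, `age`,
#'   `estimate`, `lo95`, `hi95`.
#' @export
marginal_means <- function(fit, ages = 2:7, sexes = NULL,
                           policy = c("reference", "population")) {
  policy <- match.arg(policy)
  if (fit$degenerate) abort_arg("cannot compute marginal means for a degenerate fit.")
  if (!fit$converged) warning("model did not converge; marginal means may be unreliable.")
  if (any(ages < fit$age_range[1] - 1e-8) || any(ages > fit$age_range[2] + 1e-8)) {
    warning("age grid extends beyond the fitted age range; estimates are extrapolated.")
  }
  if (is.null(sexes)) sexes <- fit$xlevels[[fit$sex_col]]
  grid <- tidyr::expand_grid(age = ages, sex = sexes)

  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))

  X <- purrr::map(seq_len(nrow(grid)), function(i) {
    if (policy == "reference") {
      nd <- tibble::as_tibble(c(
        setNames(list(grid$age[i]), fit$age_col),
        setNames(
          list(factor(grid$sex[i], levels = fit$xlevels[[fit$sex_col]])),
          fit$sex_col
        ),
        fit$cov_reference
      ))
      fixed_design(fit, nd)
    } else {
      nd <- fit$cov_rows_full
      nd[[fit$age_col]] <- grid$age[i]
      nd[[fit$sex_col]] <- factor(grid$sex[i], levels = fit$xlevels[[fit$sex_col]])
      matrix(colMeans(fixed_design(fit, nd)), nrow = 1)
    }
  })
  X <- do.call(rbind, X)

  est <- as.numeric(X %*% beta)
  se <- sqrt(rowSums((X %*% V) * X))
  zc <- qnorm(0.975)
  lo <- est - zc * se
  hi <- est + zc * se
  if (fit$family == "binomial") {
    est <- plogis(est); lo <- plogis(lo); hi <- plogis(hi)
  }
  out <- tibble::tibble(
    outcome = fit$outcome, sex = grid$sex, age = grid$age,
    estimate = est, lo95 = lo, hi95 = hi
  )
  class(out) <- c("marginal_means", class(out))
  attr(out, "policy") <- policy
  out
}

#' Wald joint test of a coefficient block
#'
#' Tests `beta_block = 0` with the statistic
#' `t(beta) %*% solve(V) %*% beta` referred to a chi-square distribution
#' with as many degrees of freedom as coefficients in the block. The usual
#' use is the age-by-sex interaction block
#' (`pattern = ":sex|sex.*:"`, the default).
#'
#' @param fit A `trajectory_fit`.
#' @param pattern Regular expression selecting coefficient names; ignored
#'   when `terms` is given.
#' @param terms Explicit character vector of coefficient names.
#'
#' @return One-row tibble: `statistic`, `df`, `p.value`, `terms`.
#' @export
wald_joint_test <- function(fit, pattern = ":", terms = NULL) {
  if (fit$degenerate) abort_arg("degenerate fit: nothing to test.")
  beta <- lme4::fixef(fit$model)
  V <- as.matrix(vcov(fit$model))
  if (is.null(terms)) terms <- names(beta)[grepl(pattern, names(beta))]
  if (length(terms) == 0) abort_arg("empty coefficient block.")
  if (!all(terms %in% names(beta))) abort_arg("unknown coefficient names.")
  b <- beta[terms]
  Vb <- V[terms, terms, drop = FALSE]
  if (rcond(Vb) < 1e-12) abort_arg("covariance sub-block is singular.")
  stat <- as.numeric(t(b) %*% solve(Vb, b))
  df <- length(terms)
  tibble::tibble(
    statistic = stat, df = df,
    p.value = pchisq(stat, df, lower.tail = FALSE),
    terms = paste(terms, collapse = ", ")
  )
}

#' Standardised effect size (Cohen's d)
#'
#' @param delta Mean difference, min/day.
#' @param sd Standard deviation, min/day (> 0).
#'
#' @return `delta / sd` at full precision.
#' @export
#'
#' @examples
#' round(cohens_d(5, 42), 2) # 0.12
cohens_d <- function(delta, sd) {
  if (any(sd <= 0)) abort_arg("sd must be > 0.")
  delta / sd
}

#' Two-group power for a mean difference (normal approximation)
#'
#' Design-exploration utility: power to detect a mean difference `delta`
#' between two independent groups of size `n_per_group` with common SD
#' `sd`, two-sided alpha.
#'
#' @param delta Mean difference.
#' @param sd Common standard deviation (> 0).
#' @param n_per_group Group size.
#' @param alpha Two-sided significance level (default 0.05).
#'
#' @return Approximate power in `[0, 1]`.
#' @export
power_normal_approx <- function(delta, sd, n_per_group, alpha = 0.05) {
  if (any(sd <= 0)) abort_arg("sd must be > 0.")
  se <- sd * sqrt(2 / n_per_group)
  zc <- qnorm(1 - alpha / 2)
  z <- abs(delta) / se
  pnorm(z - zc) + pnorm(-z - zc)
}

#' Composite behaviour sums
#'
#' Energetic play is the sum of walking, running and moderate-vigorous
#' activities and games; total physical activity is energetic play plus
#' light-intensity activities and games.
#'
#' @param lpa Light-intensity activity, min/day.
#' @param walk,run,mv_act_g Component minutes (ignored when
#'   `energetic_play` is supplied directly).
#' @param energetic_play Optional: energetic play, min/day.
#'
#' @return Tibble with `energetic_play` and `total_pa`.
#' @export
#'
#' @examples
#' sum_composites(lpa = 320.7, energetic_play = 34.7) # total_pa 355.4
sum_composites <- function(lpa, walk = 0, run = 0, mv_act_g = 0,
                           energetic_play = NULL) {
  if (is.null(energetic_play)) energetic_play <- walk + run + mv_act_g
  if (any(c(lpa, walk, run, mv_act_g, energetic_play) < 0)) {
    abort_arg("component minutes must be non-negative.")
  }
  tibble::tibble(
    energetic_play = energetic_play,
    total_pa = lpa + energetic_play
  )
}
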