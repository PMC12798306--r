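#' Specification of the within-between income-health model
#'
#' Describes the regression of an SF-12 component score on the within and
#' between components of (transformed) net equivalised household income plus
#' control covariates, estimated with person-level random intercepts
#' (Mundlak-equivalent within-between formulation) or pooled OLS with
#' cluster-robust standard errors as a cross-check.
#'
#' @param outcome `"MCS"` (mental component summary) or `"PCS"` (physical).
#' @param income_transform `"log"` (GBP 1 floor) or `"linear"`.
#' @param controls Character vector of covariate column names present in the
#'   panel (e.g. sex, age band, region, education, attrition flag).
#' @param include_lagged_case If `TRUE`, a binary indicator of having been a
#'   case at the previous wave enters as a covariate and the first wave of
#'   every person is dropped from estimation.
#' @param estimator `"random_effects"` (lme4) or `"pooled_ols_clustered"`.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("MCS", "PCS"),
                       income_transform = c("log", "linear"),
                       controls = c("sex"),
                       include_lagged_case = FALSE,
                       estimator = c("random_effects",
                                     "pooled_ols_clustered")) {
  structure(
    list(outcome = match.arg(outcome),
         income_transform = match.arg(income_transform),
         controls = controls,
         include_lagged_case = include_lagged_case,
         estimator = match.arg(estimator)),
    class = "model_spec"
  )
}

#' Decompose panel income into between and within components
#'
#' Adds `x_between` (the person's mean transformed income over all waves)
#' and `x_within` (the occasion's deviation from that mean) to a balanced
#' panel. By construction the per-person mean of `x_within` is zero and
#' `x_between + x_within` reconstructs the transformed income series.
#'
#' @param panel Balanced panel with `person_id`, `wave`, `net_equiv_income`.
#' @param transform `"log"` (applied to income floored at GBP 1) or
#'   `"linear"`.
#' @return The panel with `x_between` and `x_within` columns appended.
#' @export
decompose_income <- function(panel, transform = c("log", "linear")) {
  transform <- match.arg(transform)
  counts <- table(panel$person_id)
  if (length(unique(counts)) != 1 || any(counts < 2)) {
    stop("panel is not balanced: every person must appear in every wave ",
         "(and at least twice)", call. = FALSE)
  }
  if (anyDuplicated(panel[c("person_id", "wave")])) {
    stop("duplicate person-wave records", call. = FALSE)
  }
  x <- transform_income(panel$net_equiv_income, transform)
  xbar <- stats::ave(x, panel$person_id)
  panel$x_between <- xbar
  panel$x_within <- x - xbar
  panel
}

outcome_column <- function(outcome) c(MCS = "mcs", PCS = "pcs")[[outcome]]

lag_column <- function(outcome) {
  c(MCS = "prior_case_mcs", PCS = "prior_case_pcs")[[outcome]]
}

# Build the estimation frame and design matrix for a model spec. Returns
# the model matrix, response, person ids, the control formula and the
# factor levels needed to rebuild the design on new data.
build_design <- function(panel, spec) {
  if (!all(c("x_between", "x_within") %in% names(panel))) {
    panel <- decompose_income(panel, spec$income_transform)
  }
  missing_ctrl <- setdiff(spec$controls, names(panel))
  if (length(missing_ctrl)) {
    stop("controls not found in panel: ",
         paste(missing_ctrl, collapse = ", "), call. = FALSE)
  }
  rhs <- c("x_within", "x_between", spec$controls)
  if (spec$include_lagged_case) {
    lc <- lag_column(spec$outcome)
    if (!lc %in% names(panel)) stop("panel lacks ", lc, call. = FALSE)
    panel <- panel[panel$wave > min(panel$wave), , drop = FALSE]
    rhs <- c(rhs, lc)
  }
  ycol <- outcome_column(spec$outcome)
  used <- c(ycol, rhs, "person_id")
  cc <- stats::complete.cases(panel[used])
  n_dropped <- sum(!cc)
  panel <- panel[cc, , drop = FALSE]
  for (v in spec$controls) {
    if (is.character(panel[[v]])) panel[[v]] <- factor(panel[[v]])
  }
  f <- stats::reformulate(rhs)
  mf <- stats::model.frame(f, data = panel)
  X <- stats::model.matrix(f, mf)
  list(X = X, y = panel[[ycol]], person = panel$person_id,
       data = panel, formula = f, rhs = rhs,
       xlevels = stats::.getXlevels(stats::terms(f), mf),
       n_dropped_na = n_dropped)
}

check_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("collinear design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  q
}

# CR1 cluster-robust covariance for OLS.
cluster_vcov <- function(X, resid, cluster) {
  p <- ncol(X)
  n <- nrow(X)
  g <- length(unique(cluster))
  Xe <- rowsum(X * resid, cluster)
  bread <- chol2inv(chol(crossprod(X)))
  meat <- crossprod(Xe)
  adj <- g / (g - 1) * (n - 1) / (n - p)
  adj * bread %*% meat %*% bread
}

#' Fit the within-between income-health model
#'
#' Regresses the chosen SF-12 component score on the within and between
#' income components plus controls (and optionally the lagged case
#' indicator), either with person-level random intercepts via [lme4::lmer()]
#' or as pooled OLS with person-clustered robust standard errors. If the
#' within component has zero variance its coefficient is reported as `NA`
#' (undefined), not zero.
#'
#' @param panel Balanced panel (decomposed columns are added if absent).
#' @param spec A [model_spec()].
#' @return Object of class `coefficient_set`: point estimates
#'   (`beta_within`, `beta_between`, `intercept`, `control_coefficients`),
#'   standard errors, sample sizes, and the metadata needed to evaluate the
#'   linear predictor on new data. Confidence intervals are `NA` until
#'   [bootstrap_ci()] is run.
#' @export
fit_within_between <- function(panel, spec) {
  stopifnot(inherits(spec, "model_spec"))
  d <- build_design(panel, spec)
  zero_within <- stats::var(d$X[, "x_within"]) == 0
  X <- d$X
  if (zero_within) X <- X[, colnames(X) != "x_within", drop = FALSE]
  q <- check_rank(X)

  if (spec$estimator == "pooled_ols_clustered") {
    beta <- qr.coef(q, d$y)
    resid <- d$y - X %*% beta
    V <- cluster_vcov(X, as.vector(resid), d$person)
    se <- sqrt(diag(V))
    names(se) <- names(beta)
    coefs <- beta
  } else {
    dat <- d$data
    dat$.y <- d$y
    rhs <- d$rhs
    if (zero_within) rhs <- setdiff(rhs, "x_within")
    fml <- stats::as.formula(
      paste(".y ~", paste(rhs, collapse = " + "), "+ (1 | person_id)"))
    fit <- lme4::lmer(fml, data = dat,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    coefs <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    names(se) <- names(coefs)
  }

  bw <- if (zero_within) NA_real_ else unname(coefs[["x_within"]])
  structure(
    list(outcome = spec$outcome,
         transform = spec$income_transform,
         beta_within = bw,
         beta_between = unname(coefs[["x_between"]]),
         intercept = unname(coefs[["(Intercept)"]]),
         control_coefficients = coefs[setdiff(names(coefs),
                                              c("(Intercept)", "x_within",
                                                "x_between"))],
         coefficients = coefs,
         se = se,
         ci_lower = NULL, ci_upper = NULL,
         n_individuals = length(unique(d$person)),
         n_observations = length(d$y),
         n_dropped_na = d$n_dropped_na,
         bootstrap_reps = 0L,
         bootstrap_draws = NULL,
         spec = spec,
         xlevels = d$xlevels),
    class = "coefficient_set"
  )
}

#' Bootstrap confidence intervals for the within-between model
#'
#' Resamples individuals (each with all their waves) with replacement,
#' refits the model on every replicate, and returns percentile 2.5/97.5
#' bounds for every coefficient. Replicates with a degenerate (rank
#' deficient) design are dropped and counted; more than 5% dropped is an
#' error. Fully seeded and reproducible.
#'
#' @inheritParams fit_within_between
#' @param reps Number of bootstrap repetitions (>= 2; the reference analysis
#'   uses 1,000).
#' @param seed Integer seed for the resampling.
#' @return A `coefficient_set` (as from [fit_within_between()]) with
#'   `ci_lower`, `ci_upper`, `bootstrap_reps` and the replicate coefficient
#'   draws in `bootstrap_draws` filled in.
#' @export
bootstrap_ci <- function(panel, spec, reps = 1000, seed = 1) {
  if (reps < 2) stop("reps must be >= 2", call. = FALSE)
  point <- fit_within_between(panel, spec)
  d <- build_design(panel, spec)
  persons <- unique(d$person)
  np <- length(persons)
  rowidx <- split(seq_along(d$person), d$person)[as.character(persons)]
  p <- ncol(d$X)
  use_ols <- spec$estimator == "pooled_ols_clustered"

  draws <- matrix(NA_real_, reps, p, dimnames = list(NULL, colnames(d$X)))
  dropped <- 0L
  with_seed(seed, {
    for (r in seq_len(reps)) {
      ids <- sample.int(np, np, replace = TRUE)
      rows <- unlist(rowidx[ids], use.names = FALSE)
      Xr <- d$X[rows, , drop = FALSE]
      q <- qr(Xr)
      if (q$rank < p) {
        dropped <- dropped + 1L
        next
      }
      if (use_ols) {
        draws[r, ] <- qr.coef(q, d$y[rows])
      } else {
        dat <- d$data[rows, , drop = FALSE]
        dat$.y <- d$y[rows]
        dat$person_id <- rep(seq_len(np), lengths(rowidx[ids]))
        fml <- stats::as.formula(
          paste(".y ~", paste(d$rhs, collapse = " + "), "+ (1 | person_id)"))
        fit <- suppressMessages(suppressWarnings(
          lme4::lmer(fml, data = dat,
                     control = lme4::lmerControl(calc.derivs = FALSE))))
        fx <- lme4::fixef(fit)
        draws[r, match(names(fx), colnames(draws))] <- fx
      }
    }
  })
  if (dropped / reps > 0.05) {
    stop(dropped, "/", reps, " bootstrap replicates had degenerate designs",
         call. = FALSE)
  }
  draws <- draws[stats::complete.cases(draws), , drop = FALSE]
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  point$ci_lower <- ci[1, ]
  point$ci_upper <- ci[2, ]
  point$bootstrap_reps <- nrow(draws)
  point$bootstrap_dropped <- dropped
  point$bootstrap_draws <- draws
  point
}

#' Evaluate a fitted model's linear predictor on new data
#'
#' Computes `intercept + beta_between * x_between + beta_within * x_within +
#' controls` for each row of `data`, using the factor levels recorded at fit
#' time. Used to impute baseline scores for a cross-sectional population
#' (where `x_within = 0`).
#'
#' @param coeffs A `coefficient_set`.
#' @param data Data frame carrying every control covariate the model used.
#' @param x_between Transformed-income between component per row.
#' @param x_within Within component per row (default 0).
#' @param beta_between Optional replacement for the point `beta_between`
#'   (used when propagating bootstrap replicates).
#' @return Numeric vector of predicted scores.
#' @export
linear_predictor <- function(coeffs, data, x_between, x_within = 0,
                             beta_between = NULL) {
  stopifnot(inherits(coeffs, "coefficient_set"))
  ctrl <- coeffs$spec$controls
  missing_ctrl <- setdiff(ctrl, names(data))
  if (length(missing_ctrl)) {
    stop("missing covariate: ", paste(missing_ctrl, collapse = ", "),
         call. = FALSE)
  }
  lp <- rep(coeffs$intercept, nrow(data))
  if (length(ctrl)) {
    for (v in ctrl) {
      if (v %in% names(coeffs$xlevels)) {
        data[[v]] <- factor(data[[v]], levels = coeffs$xlevels[[v]])
        if (anyNA(data[[v]])) {
          stop("covariate ", v, " has levels unseen at fit time",
               call. = FALSE)
        }
      }
    }
    mm <- stats::model.matrix(stats::reformulate(ctrl), data = data,
                              xlev = coeffs$xlevels)
    keep <- intersect(colnames(mm), names(coeffs$control_coefficients))
    lp <- lp + as.vector(mm[, keep, drop = FALSE] %*%
                           coeffs$control_coefficients[keep])
  }
  # lagged-case models are evaluated at 'not a case in the prior period'
  # unless the indicator column is supplied with the new data
  lg <- lag_column(coeffs$outcome)
  lgname <- paste0(lg, "TRUE")
  if (lgname %in% names(coeffs$control_coefficients) && lg %in% names(data)) {
    lp <- lp + coeffs$control_coefficients[[lgname]] * as.numeric(data[[lg]])
  }
  bb <- beta_between %||% coeffs$beta_between
  bw <- if (is.na(coeffs$beta_within %||% NA_real_)) 0 else coeffs$beta_within
  lp + bb * x_between + bw * x_within
}

#' @export
print.coefficient_set <- function(x, ...) {
  cat(sprintf("<coefficient_set> %s ~ %s income (%s)\n", x$outcome,
              x$transform, x$spec$estimator))
  fmt <- function(b, nm) {
    ci <- if (!is.null(x$ci_lower) && nm %in% names(x$ci_lower)) {
      sprintf(" [%.3f, %.3f]", x$ci_lower[[nm]], x$ci_upper[[nm]])
    } else ""
    se <- if (nm %in% names(x$se)) x$se[[nm]] else NA_real_
    sprintf("%.4f (se %.4f)%s", b, se, ci)
  }
  cat("  beta_within: ",
      if (is.na(x$beta_within)) "undefined (zero within-variance)"
      else fmt(x$beta_within, "x_within"), "\n", sep = "")
  cat("  beta_between: ", fmt(x$beta_between, "x_between"), "\n", sep = "")
  cat(sprintf("  n = %d individuals, %d observations; bootstrap reps: %d\n",
              x$n_individuals, x$n_observations, x$bootstrap_reps))
  invisible(x)
}

#' Serialise a coefficient set to JSON
#'
#' Writes the contract consumed by the health-impact stage: coefficients,
#' standard errors, percentile CIs, bootstrap draws and fit metadata.
#'
#' @param coeffs A `coefficient_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coefficient_set <- function(coeffs, path) {
  obj <- coeffs
  obj$spec <- unclass(obj$spec)
  # named atomic vectors serialise as JSON objects, not bare arrays
  for (nm in c("control_coefficients", "coefficients", "se",
               "ci_lower", "ci_upper")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- as.list(obj[[nm]])
  }
  obj$bootstrap_draws <- if (!is.null(obj$bootstrap_draws)) {
    as.data.frame(obj$bootstrap_draws)
  }
  jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a coefficient set from JSON
#'
#' @param path File written by [write_coefficient_set()].
#' @return A `coefficient_set`.
#' @export
read_coefficient_set <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$spec <- structure(obj$spec, class = "model_spec")
  if (!is.null(obj$bootstrap_draws)) {
    obj$bootstrap_draws <- as.matrix(obj$bootstrap_draws)
  }
  for (nm in c("control_coefficients", "coefficients", "se",
               "ci_lower", "ci_upper")) {
    if (!is.null(obj[[nm]])) obj[[nm]] <- unlist(obj[[nm]])
  }
  structure(obj, class = "coefficient_set")
}
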