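#' Symbolic specification of a precision-weighted mixed model
#'
#' Describes a Gaussian linear mixed model by its response, fixed terms
#' (mains and pairwise interactions written `"a:b"`), random-intercept
#' grouping factors and weight column. Interactions must come with both
#' parent mains (marginality); random factors may not appear among the
#' fixed terms.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed terms; may be empty
#'   (intercept-only model).
#' @param random Character vector of random-intercept grouping factors
#'   (fitted as `(1 | factor)`), possibly empty.
#' @param weights Name of the precision-weight column, or `NULL` for an
#'   unweighted model.
#' @param method `"ML"` (default, comparable across fixed structures) or
#'   `"REML"`.
#' @return A `model_spec` object.
#' @examples
#' model_spec("gdp", c("abs_latitude", "kingdom", "abs_latitude:kingdom"),
#'            random = c("species", "marker_type"))
#' @export
model_spec <- function(response, fixed = character(), random = character(),
                       weights = "weight", method = c("ML", "REML")) {
  method <- match.arg(method)
  fixed <- unique(as.character(fixed))
  random <- unique(as.character(random))
  ints <- fixed[grepl(":", fixed, fixed = TRUE)]
  mains <- setdiff(fixed, ints)
  for (tm in ints) {
    parents <- strsplit(tm, ":", fixed = TRUE)[[1]]
    if (length(parents) != 2) {
      abort(paste0("only pairwise interactions supported: ", tm))
    }
    if (!all(parents %in% mains)) {
      abort(paste0("interaction ", tm,
                   " violates marginality: both mains must be present"))
    }
  }
  if (length(intersect(random, c(mains, unlist(strsplit(ints, ":"))))) > 0) {
    abort("random factors must be disjoint from fixed terms")
  }
  structure(
    list(response = response, fixed = fixed, random = random,
         weights = weights, method = method),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", deparse1(spec_formula(x)), "\n",
      if (!is.null(x$weights)) paste0("  weights: ", x$weights, "\n"),
      "  method: ", x$method, "\n", sep = "")
  invisible(x)
}

# canonical form of a term: interaction parents sorted
canonical_term <- function(terms) {
  vapply(terms, function(tm) {
    if (grepl(":", tm, fixed = TRUE)) {
      paste(sort(strsplit(tm, ":", fixed = TRUE)[[1]]), collapse = ":")
    } else tm
  }, character(1), USE.NAMES = FALSE)
}

#' Model formula of a `model_spec`
#' @param spec A [model_spec()].
#' @return A formula combining fixed terms and `(1 | g)` random intercepts.
#' @export
spec_formula <- function(spec) {
  rhs <- c(if (length(spec$fixed) == 0) "1" else spec$fixed,
           sprintf("(1 | %s)", spec$random))
  as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Latitude-gradient model specifications
#'
#' The two descriptive diversity-gradient models: at `kingdom` level, the
#' harmonized response against `|latitude| * kingdom` with species and
#' marker-type random intercepts; at `phylum` level, kingdom is replaced
#' by phylum as the interacting predictor and moves into the random part
#' to absorb non-independence within kingdoms.
#'
#' @param level `"kingdom"` or `"phylum"`.
#' @return A [model_spec()].
#' @export
build_latitude_spec <- function(level = c("kingdom", "phylum")) {
  level <- match.arg(level)
  if (level == "kingdom") {
    model_spec("gdp",
               c("abs_latitude", "kingdom", "abs_latitude:kingdom"),
               random = c("species", "marker_type"))
  } else {
    model_spec("gdp",
               c("abs_latitude", "phylum", "abs_latitude:phylum"),
               random = c("species", "marker_type", "kingdom"))
  }
}

#' Fit a precision-weighted Gaussian linear mixed model
#'
#' Maximizes the Gaussian (restricted) likelihood of the model described
#' by `spec`, with independent random intercepts and residual variance
#' inversely proportional to the row weight, `Var(e_i) = sigma^2 / w_i`.
#' With no random factors the model reduces to (weighted) least squares.
#'
#' When a random-intercept variance is estimated at the zero boundary the
#' fit is flagged (`boundary`); with `boundary_fallback = TRUE` a boundary
#' marker-type variance triggers an automatic refit with marker type moved
#' to the fixed effects. The fallback is off by default so that AICc stays
#' comparable across an enumerated model set.
#'
#' @param data Data frame holding the response, covariates, grouping
#'   factors and weight column.
#' @param spec A [model_spec()].
#' @param method Override the spec's estimation method (`"ML"`/`"REML"`).
#' @param boundary_fallback Refit with marker type as a fixed effect when
#'   its random variance hits the boundary (default FALSE).
#' @return A `gdp_fit` object: coefficient table, random-intercept
#'   variances `tau2`, residual variance `sigma2` (at unit weight),
#'   log-likelihood, `n`, parameter count `k`, `AICc`, Nakagawa `r2m` /
#'   `r2c`, fitted values, residuals and convergence flags. Supports
#'   [tidy()], [glance()] and `print()`.
#' @export
fit_weighted_lmm <- function(data, spec, method = NULL,
                             boundary_fallback = FALSE) {
  stopifnot(is.data.frame(data), inherits(spec, "model_spec"))
  method <- method %||% spec$method
  vars <- unique(c(spec$response,
                   unlist(strsplit(spec$fixed, ":", fixed = TRUE)),
                   spec$random, spec$weights))
  missing_cols <- setdiff(vars, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- as.data.frame(data)[stats::complete.cases(
    as.data.frame(data)[, vars, drop = FALSE]), , drop = FALSE]
  w <- if (is.null(spec$weights)) rep(1, nrow(data)) else data[[spec$weights]]
  if (any(w <= 0)) abort("weights must be positive")
  for (g in spec$random) {
    if (length(unique(data[[g]])) < 2) {
      abort(paste0("random factor ", g, " has < 2 levels"))
    }
    data[[g]] <- factor(data[[g]])
  }

  fixed_form <- as.formula(paste(
    spec$response, "~",
    if (length(spec$fixed) == 0) "1" else paste(spec$fixed, collapse = " + ")
  ))
  X <- model.matrix(fixed_form, data)
  if (qr(X)$rank < ncol(X)) {
    fit0 <- lm(fixed_form, data = data)
    aliased <- names(coef(fit0))[is.na(coef(fit0))]
    abort(paste0("rank-deficient fixed-effect design; aliased terms: ",
                 paste(aliased, collapse = ", ")))
  }

  if (length(spec$random) == 0) {
    fit <- if (is.null(spec$weights)) {
      lm(fixed_form, data = data)
    } else {
      lm(fixed_form, data = data, weights = w)
    }
    beta <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
    tau2 <- setNames(numeric(0), character(0))
    # ML residual variance at unit weight
    sigma2 <- sum(w * resid(fit)^2) / nrow(data)
    ll <- as.numeric(logLik(fit))
    k <- length(beta) + 1
    converged <- TRUE
    boundary <- FALSE
    lfit <- fit
  } else {
    form <- spec_formula(spec)
    data[["..w"]] <- w
    lfit <- lme4::lmer(form, data = data, weights = ..w,
                       REML = identical(method, "REML"),
                       control = lme4::lmerControl(
                         calc.derivs = FALSE,
                         check.conv.singular = "ignore"))
    conv_msgs <- lfit@optinfo$conv$lme4$messages
    converged <- is.null(conv_msgs) ||
      !any(grepl("failed to converge", conv_msgs, ignore.case = TRUE))
    if (!converged) {
      warn(paste0("lmer convergence warning: ",
                  paste(conv_msgs, collapse = "; ")))
    }
    beta <- lme4::fixef(lfit)
    se <- sqrt(diag(as.matrix(vcov(lfit))))
    vc <- as.data.frame(lme4::VarCorr(lfit))
    res_row <- vc$grp == "Residual"
    sigma2 <- vc$vcov[res_row]
    tau2 <- setNames(vc$vcov[!res_row], vc$grp[!res_row])
    boundary <- any(tau2 < 1e-8 * max(sigma2, 1e-12))
    ll <- as.numeric(logLik(lfit))
    k <- length(beta) + length(tau2) + 1

    if (boundary && boundary_fallback &&
        "marker_type" %in% names(tau2)[tau2 < 1e-8 * sigma2]) {
      spec2 <- model_spec(spec$response,
                          fixed = union(spec$fixed, "marker_type"),
                          random = setdiff(spec$random, "marker_type"),
                          weights = spec$weights, method = method)
      refit <- fit_weighted_lmm(data, spec2, method = method,
                                boundary_fallback = FALSE)
      refit$fallback_applied <- TRUE
      return(refit)
    }
  }

  zval <- beta / se
  coefs <- tibble::tibble(
    term = names(beta), estimate = unname(beta), std.error = unname(se),
    statistic = unname(zval), p.value = 2 * pnorm(-abs(unname(zval)))
  )
  n <- nrow(data)
  fitted_fixed <- as.numeric(X %*% beta)
  r2 <- nakagawa_r2(fitted_fixed, tau2, sigma2)

  structure(
    list(spec = spec, method = method, fit = lfit,
         coefficients = coefs, tau2 = tau2, sigma2 = sigma2,
         loglik = ll, n = n, k = k, aicc = aicc(ll, k, n),
         r2m = r2[["r2m"]], r2c = r2[["r2c"]],
         fitted = fitted(lfit), residuals = resid(lfit),
         fitted_fixed = fitted_fixed,
         converged = converged, boundary = boundary,
         fallback_applied = FALSE, data = data),
    class = "gdp_fit"
  )
}

nakagawa_r2 <- function(fitted_fixed, tau2, sigma2) {
  var_f <- if (length(fitted_fixed) > 1) var(fitted_fixed) else 0
  total <- var_f + sum(tau2) + sigma2
  if (total <= 0) abort("zero total variance; R^2 undefined")
  c(r2m = var_f / total, r2c = (var_f + sum(tau2)) / total)
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Variance-partition R-squared for Gaussian mixed models: the marginal
#' `r2m = var(X b) / (var(X b) + sum(tau2) + sigma2)` measures the share
#' explained by fixed effects; the conditional `r2c` adds the
#' random-intercept variances to the numerator. For weighted fits,
#' `sigma2` is the residual variance parameter at unit weight.
#'
#' @param fit A `gdp_fit`.
#' @return A one-row tibble with `r2m` and `r2c`.
#' @export
r2_nakagawa <- function(fit) {
  stopifnot(inherits(fit, "gdp_fit"))
  if (!fit$converged) abort("fit did not converge; R^2 not reported")
  tibble::tibble(r2m = fit$r2m, r2c = fit$r2c)
}

#' @export
print.gdp_fit <- function(x, ...) {
  cat(sprintf("<gdp_fit> %s (%s)\n", deparse1(spec_formula(x$spec)),
              x$method))
  cat(sprintf("  n = %d, k = %d, logLik = %.3f, AICc = %.3f\n",
              x$n, x$k, x$loglik, x$aicc))
  cat(sprintf("  sigma2 = %.4g; tau2: %s\n", x$sigma2,
              if (length(x$tau2) == 0) "none" else
                paste(names(x$tau2), signif(x$tau2, 4),
                      sep = " = ", collapse = ", ")))
  cat(sprintf("  R2m = %.3f, R2c = %.3f%s%s\n", x$r2m, x$r2c,
              if (x$boundary) " [variance at boundary]" else "",
              if (x$fallback_applied) " [marker fixed-effect fallback]" else ""))
  print(x$coefficients)
  invisible(x)
}

#' @method tidy gdp_fit
#' @export
tidy.gdp_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  out <- x$coefficients
  if (conf.int) {
    zq <- qnorm(1 - (1 - conf.level) / 2)
    out <- dplyr::mutate(out,
                         conf.low = .data$estimate - zq * .data$std.error,
                         conf.high = .data$estimate + zq * .data$std.error)
  }
  out
}

#' @method glance gdp_fit
#' @export
glance.gdp_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n, k = x$k, logLik = x$loglik, AICc = x$aicc,
    sigma2 = x$sigma2, r2m = x$r2m, r2c = x$r2c,
    converged = x$converged, boundary = x$boundary
  )
}

#' Per-group slopes of a covariate from an interaction fit
#'
#' For a model containing `covariate`, a categorical `group` main effect
#' and their interaction, returns each group's slope of the covariate:
#' the reference group's slope is the base coefficient, other groups add
#' their interaction coefficient, with standard errors propagated through
#' the full fixed-effect covariance (`c' V c`) and normal 95% CIs.
#'
#' @param fit A `gdp_fit` of a model with the `covariate * group`
#'   interaction.
#' @param group Name of the grouping factor (e.g. `"phylum"`).
#' @param covariate Name of the continuous covariate (default
#'   `"abs_latitude"`).
#' @param conf.level Confidence level (default 0.95).
#' @return Tibble with `group`, `level`, `slope`, `std.error`, `conf.low`,
#'   `conf.high`, `p.value`.
#' @export
extract_group_slopes <- function(fit, group, covariate = "abs_latitude",
                                 conf.level = 0.95) {
  stopifnot(inherits(fit, "gdp_fit"))
  beta <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  V <- as.matrix(vcov(fit$fit))
  if (!covariate %in% names(beta)) {
    abort(paste0("covariate ", covariate, " not among coefficients"))
  }
  levs <- levels(factor(fit$data[[group]]))
  has_int <- any(grepl(paste0(covariate, ":", group), names(beta),
                       fixed = TRUE) |
                   grepl(paste0(group, ".*:", covariate), names(beta)))
  if (!has_int) {
    abort(paste0("no ", covariate, ":", group, " interaction in the model"))
  }
  zq <- qnorm(1 - (1 - conf.level) / 2)
  rows <- lapply(levs, function(lv) {
    cvec <- setNames(numeric(length(beta)), names(beta))
    cvec[covariate] <- 1
    nm1 <- paste0(covariate, ":", group, lv)
    nm2 <- paste0(group, lv, ":", covariate)
    nm <- c(nm1, nm2)[c(nm1, nm2) %in% names(beta)]
    if (length(nm) == 1) cvec[nm] <- 1
    est <- sum(cvec * beta)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    tibble::tibble(group = group, level = lv, slope = est, std.error = se,
                   conf.low = est - zq * se, conf.high = est + zq * se,
                   p.value = 2 * pnorm(-abs(est / se)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("group_slopes", class(out))
  out
}
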