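#' Benesi-Hildebrand double-reciprocal fit
#'
#' Estimates the apparent 1:1 association constant Ka from a titration of
#' absorbance change against host concentration. The 1:1 isotherm
#' `dA = eps_c * l * [S] * Ka * [CD0] / (1 + Ka * [CD0])` linearizes exactly
#' as `[S]/dA = 1/(eps_c * l * Ka) * (1/[CD0]) + 1/(eps_c * l)`, so an
#' ordinary least-squares line of `y = [S]/dA` on `x = 1/[CD0]` yields
#' `Ka = intercept/slope` and `eps_c * l = 1/intercept`. For a mixture of
#' isomeric hosts the recovered Ka is the harmonic mean of the individual
#' constants. The Ka standard error comes from first-order (delta-method)
#' propagation of a heteroscedasticity-robust (HC3) regression covariance:
#' the reciprocal transform concentrates the absorbance noise on the
#' largest-`1/[CD0]` points, so the homoscedastic OLS covariance badly
#' understates the intercept uncertainty.
#'
#' @param data Tibble with columns `cd0` (initial host concentration, M,
#'   strictly increasing and positive) and `delta_a` (absorbance change).
#' @param s_total Total guest concentration, M.
#' @param path_length Optical path length, cm (informational; the fit works
#'   on `[S]/dA` directly).
#' @return Object of class `bh_fit` with elements `ka` (M^-1), `ka_stderr`,
#'   `eps_c_l` (M^-1), `slope`, `intercept`, `r_squared`, `n`, `data`, and
#'   the underlying `lm` fit.
#' @export
bh_fit <- function(data, s_total, path_length = 1) {
  if (!all(c("cd0", "delta_a") %in% names(data))) {
    abort("data needs columns cd0 and delta_a")
  }
  ok <- data$delta_a > 0
  d <- data[ok, ]
  if (nrow(d) < 3) abort("need at least 3 points with delta_a > 0")
  if (any(d$cd0 <= 0)) abort("cd0 must be positive")
  if (is.unsorted(data$cd0, strictly = TRUE)) {
    abort("cd0 must be strictly increasing")
  }
  if (!is.numeric(s_total) || s_total <= 0) abort("s_total must be > 0")
  x <- 1 / d$cd0
  y <- s_total / d$delta_a
  fit <- lm(y ~ x)
  b <- unname(coef(fit))
  intercept <- b[1]
  slope <- b[2]
  if (slope <= 0 || intercept <= 0) {
    abort("fit invalid: non-positive slope or intercept (no real Ka)")
  }
  ka <- intercept / slope
  V <- suppressWarnings(sandwich::vcovHC(fit, type = "HC3"))
  # delta method on g(b0, b1) = b0/b1: grad = (1/b1, -b0/b1^2)
  grad <- c(1 / slope, -intercept / slope^2)
  ka_var <- drop(t(grad) %*% V %*% grad)
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(list(
    ka = ka, ka_stderr = sqrt(pmax(ka_var, 0)), eps_c_l = 1 / intercept,
    slope = slope, intercept = intercept, r_squared = r2,
    n = nrow(d), s_total = s_total, path_length = path_length,
    data = tibble::tibble(cd0 = d$cd0, delta_a = d$delta_a, x = x, y = y),
    fit = fit
  ), class = "bh_fit")
}

#' @export
print.bh_fit <- function(x, ...) {
  cat(sprintf(
    "<bh_fit> Ka = %.3f +/- %.3f M^-1, eps_c*l = %.4g M^-1, R^2 = %.5f (n = %d)\n",
    x$ka, x$ka_stderr, x$eps_c_l, x$r_squared, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bh_fit <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(
    term = c("intercept", "slope", "ka", "eps_c_l"),
    estimate = c(x$intercept, x$slope, x$ka, x$eps_c_l),
    std.error = c(s[1, 2], s[2, 2], x$ka_stderr, NA_real_)
  )
}

#' @exportS3Method generics::glance
glance.bh_fit <- function(x, ...) {
  tibble::tibble(
    ka = x$ka, ka_stderr = x$ka_stderr, eps_c_l = x$eps_c_l,
    r.squared = x$r_squared, nobs = x$n
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.bh_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = expression(1 / "[CD]"[0] ~ (M^-1)),
      y = expression("[S]" / Delta * A ~ (M)),
      title = sprintf("Benesi-Hildebrand fit: Ka = %.2f M^-1", object$ka)
    ) +
    ggplot2::theme_minimal()
}

#' Classify a phase-solubility profile
#'
#' Fits the quadratic `S = a + b*[CD] + c*[CD]^2` and classifies the
#' Higuchi-Connors diagram type from the fitted coefficients: `Ap` when the
#' curvature `c` is significantly positive (t-test at `alpha`, two-sided
#' p-value with positive sign), `AN` when significantly negative, `AL` when
#' the curvature is not significant but the linear slope `b` is
#' significantly positive, and `flat` otherwise. Positive curvature is the
#' signature of higher-order (1:2 and beyond) host stoichiometries; a linear
#' diagram indicates apparent 1:1 complexation; a flat diagram, no
#' solubilization.
#'
#' @param data Tibble with columns `cd_conc` (host concentration, M) and
#'   `solubility` (guest solubility; any consistent unit).
#' @param alpha Significance level for the coefficient t-tests.
#' @return Object of class `cd_phase_profile`: `classification`, `slope`,
#'   `curvature`, `curvature_p`, `slope_p`, `alpha`, `data`, `fit`.
#' @export
classify_phase_solubility <- function(data, alpha = 0.05) {
  if (!all(c("cd_conc", "solubility") %in% names(data))) {
    abort("data needs columns cd_conc and solubility")
  }
  if (nrow(data) < 4) abort("need at least 4 points to test curvature")
  fit <- lm(solubility ~ cd_conc + I(cd_conc^2), data = data)
  s <- suppressWarnings(summary(fit))$coefficients
  b <- s["cd_conc", "Estimate"]
  b_p <- s["cd_conc", "Pr(>|t|)"]
  cc <- s["I(cd_conc^2)", "Estimate"]
  c_p <- s["I(cd_conc^2)", "Pr(>|t|)"]
  scale_s <- max(abs(data$solubility), .Machine$double.eps)
  exact <- sqrt(mean(stats::residuals(fit)^2)) <= 1e-10 * scale_s
  if (exact) {
    # zero residual variance (noiseless profile): t statistics are
    # undefined, so judge the terms by their contribution to the curve
    curved <- abs(cc) * max(data$cd_conc)^2 > 1e-9 * scale_s
    linear <- abs(b) * max(data$cd_conc) > 1e-9 * scale_s && b > 0
  } else {
    curved <- is.finite(c_p) && c_p < alpha
    linear <- is.finite(b_p) && b_p < alpha && b > 0
  }
  classification <- if (curved && cc > 0) {
    "Ap"
  } else if (curved && cc < 0) {
    "AN"
  } else if (linear) {
    "AL"
  } else {
    "flat"
  }
  structure(list(
    classification = classification, slope = b, curvature = cc,
    curvature_p = c_p, slope_p = b_p, alpha = alpha,
    data = tibble::as_tibble(data), fit = fit
  ), class = "cd_phase_profile")
}

#' @export
print.cd_phase_profile <- function(x, ...) {
  cat(sprintf(
    "<cd_phase_profile> type %s (slope %.4g, curvature %.4g, p_curv %.3g)\n",
    x$classification, x$slope, x$curvature, x$curvature_p
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cd_phase_profile <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "slope", "curvature"),
    estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"],
    p.value = s[, "Pr(>|t|)"]
  )
}

#' @exportS3Method generics::glance
glance.cd_phase_profile <- function(x, ...) {
  tibble::tibble(
    classification = x$classification, slope = x$slope,
    curvature = x$curvature, curvature_p = x$curvature_p,
    nobs = nrow(x$data)
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.cd_phase_profile <- function(object, ...) {
  grid <- tibble::tibble(cd_conc = seq(min(object$data$cd_conc),
                                       max(object$data$cd_conc), length.out = 100))
  grid$solubility <- stats::predict(object$fit, grid)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$cd_conc, y = .data$solubility)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "[CD] (M)", y = "solubility",
                  title = sprintf("phase-solubility diagram: %s-type",
                                  object$classification)) +
    ggplot2::theme_minimal()
}

#' Sum second-order perturbation (NBO) stabilization contributions
#'
#' Adds the per-interaction E(2) donor-acceptor stabilization energies of a
#' contact and reports the total in both kJ/mol and kcal/mol
#' (1 kcal = 4.184 kJ).
#'
#' @param contributions Tibble with a column `e2_kj_mol` (>= 0); columns
#'   `donor`/`acceptor` labels are accepted and ignored. A bare numeric
#'   vector works too.
#' @return Tibble with `total_kj_mol` and `total_kcal_mol`.
#' @export
sum_nbo_contributions <- function(contributions) {
  e2 <- if (is.data.frame(contributions)) {
    if (!"e2_kj_mol" %in% names(contributions)) {
      abort("contributions need an e2_kj_mol column")
    }
    contributions$e2_kj_mol
  } else {
    as.numeric(contributions)
  }
  if (any(e2 < 0)) abort("E(2) contributions must be non-negative")
  total <- sum(e2)
  tibble::tibble(total_kj_mol = total, total_kcal_mol = total / 4.184)
}
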