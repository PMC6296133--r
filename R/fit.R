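# Maximum likelihood estimation of the natural-history parameters.
#
# Optimization runs on a transformed scale (log for rates and r, logit for S)
# so the search is unconstrained. The objective is the mean negative
# log-likelihood per woman; gradients are central differences, the quasi-
# Newton (BFGS) solution is polished with Nelder-Mead, and the
# Karush-Kuhn-Tucker conditions (stationarity of the gradient, non-negative
# curvature of the Hessian) are checked at the optimum. Standard errors come
# from the inverse Hessian with a delta-method map back to the natural scale.

.theta_names <- function(model, partition) {
  lab <- interval_labels(partition)
  if (model == "nonhomogeneous") {
    c(paste0("lambda12", lab[-1L]), paste0("lambda23", lab), "r", "S")
  } else {
    c("lambda12", "lambda23", "r", "S")
  }
}

.theta_to_params <- function(theta, model, lambda12_fixed, L) {
  if (model == "nonhomogeneous") {
    l12 <- c(lambda12_fixed, exp(theta[seq_len(L - 1L)]))
    l23 <- exp(theta[L:(2L * L - 1L)])
    r <- exp(theta[2L * L])
    S <- stats::plogis(theta[2L * L + 1L])
  } else {
    l12 <- rep(exp(theta[1L]), L)
    l23 <- rep(exp(theta[2L]), L)
    r <- exp(theta[3L])
    S <- stats::plogis(theta[4L])
  }
  list(l12 = l12, l23 = l23, r = r, S = S)
}

.params_to_theta <- function(params, model, L) {
  l12 <- rep(params$lambda12, length.out = L)
  l23 <- rep(params$lambda23, length.out = L)
  if (model == "nonhomogeneous") {
    c(log(l12[-1L]), log(l23), log(params$r), stats::qlogis(params$S))
  } else {
    c(log(l12[1L]), log(l23[1L]), log(params$r), stats::qlogis(params$S))
  }
}

.num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

.num_hess <- function(f, x, h = 1e-4) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    for (j in seq_len(p)) {
      if (j >= i) next
      ej <- numeric(p); ej[j] <- h
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' Fit the natural-history model by maximum likelihood
#'
#' Maximizes the cohort likelihood over the transformed parameter scale. For
#' the non-homogeneous model the free parameters are the onset rates on the
#' second and later age intervals (the pre-50 onset rate is fixed at
#' \code{lambda12_fixed}, sourced externally from registry incidence), the
#' progression rates on all intervals, the ratio \code{r} and the sensitivity
#' \code{S}. The homogeneous comparator shares a single onset and a single
#' progression rate across all ages.
#'
#' @param cohort A [screening_cohort].
#' @param partition An [age_partition].
#' @param model \code{"nonhomogeneous"} (default) or \code{"homogeneous"}.
#' @param lambda12_fixed Fixed onset rate on the first age interval
#'   (non-homogeneous model only). The default 0.0015/woman-year is a
#'   synthetic stand-in for a registry-derived value and is flagged in the
#'   fit output.
#' @param init Optional [model_parameters] starting values. By default the
#'   onset rates start at the crude cancer incidence of the cohort,
#'   \code{lambda23} at 0.4 (mean sojourn time 2.5 years), \code{r} at 0.001
#'   and \code{S} at 0.9.
#' @param condition_entry Condition each woman's likelihood on the absence of
#'   a clinical diagnosis before her entry (first invitation), i.e. divide by
#'   \code{1 - P13(t0, entry)}. Defaults to \code{TRUE} because register-built
#'   cohorts (and [simulate_cohort()]) exclude women diagnosed before their
#'   first invitation; fitting the unconditioned likelihood to such
#'   left-truncated data severely biases the pre-50 progression rate and the
#'   sensitivity. Set to \code{FALSE} to reproduce the plain likelihood.
#' @param control List of optional knobs: \code{maxit_bfgs} (300),
#'   \code{maxit_nm} (2000), \code{reltol} (1e-8), \code{grad_h} (1e-6),
#'   \code{hess_h} (1e-3), \code{kkt_grad_tol} (1e-5, sup-norm of the mean
#'   per-woman score), \code{kkt_eigen_tol} (-1e-6), \code{polish} (TRUE),
#'   \code{polish_rounds} (3).
#' @return An object of class \code{nh_fit} with the estimates (a
#'   [model_parameters]), transformed- and natural-scale covariance matrices,
#'   \code{minus2loglik}, convergence and KKT diagnostics.
#' @export
fit_natural_history <- function(cohort, partition = age_partition(),
                                model = c("nonhomogeneous", "homogeneous"),
                                lambda12_fixed = 0.0015, init = NULL,
                                condition_entry = TRUE, control = list()) {
  model <- match.arg(model)
  stopifnot(inherits(cohort, "screening_cohort"))
  ctl <- utils::modifyList(
    list(maxit_bfgs = 300L, maxit_nm = 2000L, reltol = 1e-8, grad_h = 1e-6,
         hess_h = 1e-3, kkt_grad_tol = 1e-5, kkt_eigen_tol = -1e-6,
         polish = TRUE, polish_rounds = 3L), control)
  L <- partition$n_intervals
  if (model == "nonhomogeneous" && L < 2L)
    stop("the non-homogeneous model needs at least two age intervals")
  cc <- cohort$cc
  n <- cc$n

  if (is.null(init)) {
    py <- pmax(cc$censor_age - cc$entry_age, 0)
    crude <- sum(cc$outcome != "censored") / max(sum(py), 1)
    init <- model_parameters(lambda12 = rep(max(crude, 1e-5), L),
                             lambda23 = rep(0.4, L), r = 0.001, S = 0.9)
  }
  theta0 <- .params_to_theta(init, model, L)
  names(theta0) <- .theta_names(model, partition)

  negll <- function(theta) {
    p <- .theta_to_params(theta, model, lambda12_fixed, L)
    par <- list(l12 = p$l12, l23 = p$l23, r = p$r, S = p$S,
                cuts = partition$cutpoints, t0 = partition$t0)
    v <- -mean(.loglik_engine(cc, par, condition_entry))
    if (!is.finite(v)) 1e10 else v
  }
  if (negll(theta0) >= 1e10)
    stop("log-likelihood is not finite at the starting values; ",
         "supply a different `init`")
  gr <- function(theta) .num_grad(negll, theta, h = ctl$grad_h)

  opt <- stats::optim(theta0, negll, gr = gr, method = "BFGS",
                      control = list(maxit = ctl$maxit_bfgs,
                                     reltol = ctl$reltol))
  n_eval <- opt$counts["function"] + opt$counts["gradient"] *
    (2L * length(theta0))
  opt_converged <- opt$convergence == 0
  g <- gr(opt$par)
  # polish when the quasi-Newton run stopped early or left a non-stationary
  # gradient: alternate Nelder-Mead and short BFGS rounds until the
  # objective settles
  if (ctl$polish && (!opt_converged || max(abs(g)) > ctl$kkt_grad_tol)) {
    for (round in seq_len(ctl$polish_rounds)) {
      val0 <- opt$value
      nm <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                         control = list(maxit = ctl$maxit_nm,
                                        reltol = 1e-10))
      n_eval <- n_eval + nm$counts["function"]
      if (is.finite(nm$value) && nm$value < opt$value) {
        opt$par <- nm$par
        opt$value <- nm$value
        opt_converged <- opt_converged || nm$convergence == 0
      }
      bf <- stats::optim(opt$par, negll, gr = gr, method = "BFGS",
                         control = list(maxit = 100L, reltol = ctl$reltol))
      n_eval <- n_eval + bf$counts["function"] +
        bf$counts["gradient"] * (2L * length(theta0))
      if (is.finite(bf$value) && bf$value < opt$value) {
        opt$par <- bf$par
        opt$value <- bf$value
        opt_converged <- opt_converged || bf$convergence == 0
      }
      if (val0 - opt$value < 1e-9) break
    }
    g <- gr(opt$par)
  }

  H <- .num_hess(negll, opt$par, h = ctl$hess_h)
  eig <- eigen(H, symmetric = TRUE)
  kkt <- list(grad_sup_norm = max(abs(g)), min_eigenvalue = min(eig$values),
              ok = max(abs(g)) < ctl$kkt_grad_tol &&
                min(eig$values) >= ctl$kkt_eigen_tol)

  # invert the mean-scale Hessian through its spectrum; directions that are
  # flat to numerical precision (e.g. log r on its ridge with S) get their
  # curvature floored at 1e-8, which surfaces as an honestly enormous
  # standard error rather than a discarded covariance. A genuinely negative
  # direction (beyond the KKT tolerance) still yields no covariance.
  cov_trans <- if (min(eig$values) >= ctl$kkt_eigen_tol) {
    vals <- pmax(eig$values, 1e-8)
    V <- eig$vectors %*% (t(eig$vectors) / vals) / n
    if (any(!is.finite(V)) || any(diag(V) <= 0)) NULL else (V + t(V)) / 2
  } else NULL

  p <- .theta_to_params(opt$par, model, lambda12_fixed, L)
  est <- model_parameters(lambda12 = p$l12, lambda23 = p$l23, r = p$r, S = p$S)
  # store the deviance as a direct sum so it is bit-reproducible from the
  # estimates and the cohort
  ll_sum <- sum(.loglik_engine(cc, .par_engine(est, partition),
                               condition_entry))
  free <- names(theta0)
  natural <- c(p$l12[if (model == "nonhomogeneous") -1L else 1L][
    seq_len(if (model == "nonhomogeneous") L - 1L else 1L)],
    if (model == "nonhomogeneous") p$l23 else p$l23[1L], p$r, p$S)
  jac <- c(natural[seq_len(length(natural) - 1L)],
           p$S * (1 - p$S))  # d natural / d theta, diagonal
  cov_nat <- if (!is.null(cov_trans))
    diag(jac) %*% cov_trans %*% diag(jac) else NULL
  if (!is.null(cov_nat)) dimnames(cov_nat) <- list(free, free)
  names(natural) <- free

  structure(list(
    model = model, partition = partition, lambda12_fixed = lambda12_fixed,
    estimates = est, theta = stats::setNames(opt$par, free),
    natural = natural,
    cov_trans = cov_trans, cov_natural = cov_nat,
    loglik = ll_sum, minus2loglik = -2 * ll_sum,
    n_women = n, n_free = length(theta0), n_evaluations = unname(n_eval),
    converged = (opt_converged || kkt$ok) && is.finite(opt$value),
    kkt = kkt, kkt_ok = kkt$ok,
    boundary = list(r = p$r < 1e-7),
    condition_entry = condition_entry,
    init = init), class = "nh_fit")
}

#' @export
print.nh_fit <- function(x, ...) {
  cat("Four-state natural-history fit (", x$model, " model)\n", sep = "")
  cat("  n =", x$n_women, "women;  -2 log L =",
      format(x$minus2loglik, big.mark = ","), "\n")
  cat("  converged:", x$converged, " KKT ok:", x$kkt$ok,
      sprintf(" (|grad| = %.2e, min eig = %.2e)\n",
              x$kkt$grad_sup_norm, x$kkt$min_eigenvalue))
  if (x$model == "nonhomogeneous")
    cat("  lambda12 on ", interval_labels(x$partition)[1L],
        " fixed at ", x$lambda12_fixed, "\n", sep = "")
  if (isTRUE(x$boundary$r)) cat("  note: r estimated at the zero boundary\n")
  print(round(rbind(estimate = x$natural), 6))
  invisible(x)
}

#' @export
logLik.nh_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_free, class = "logLik")
}

#' Standard errors and Wald confidence intervals of a fit
#'
#' Transforms the inverse-Hessian covariance to the natural scale by the
#' delta method and builds symmetric Wald intervals there, truncating lower
#' bounds at zero for the non-negative rates and ratio and clipping the
#' sensitivity interval to \eqn{[0, 1]}.
#'
#' @param fit An \code{nh_fit}.
#' @param level Confidence level.
#' @return A data.frame with parameter, estimate, se, lower, upper.
#' @export
standard_errors <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nh_fit"))
  if (is.null(fit$cov_natural))
    stop("Hessian was singular or not positive definite; ",
         "no covariance is available for this fit")
  se <- sqrt(diag(fit$cov_natural))
  z <- stats::qnorm(1 - (1 - level) / 2)
  est <- fit$natural
  lower <- pmax(est - z * se, 0)
  upper <- est + z * se
  is_S <- names(est) == "S"
  upper[is_S] <- pmin(upper[is_S], 1)
  data.frame(parameter = names(est), estimate = unname(est), se = unname(se),
             lower = unname(lower), upper = unname(upper),
             row.names = NULL)
}

#' @export
summary.nh_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$cov_natural)) {
    cat("\nWald 95% intervals (natural scale):\n")
    print(standard_errors(object), digits = 4)
  } else {
    cat("\n(no covariance available: singular Hessian)\n")
  }
  invisible(object)
}

#' @export
confint.nh_fit <- function(object, parm, level = 0.95, ...) {
  se <- standard_errors(object, level = level)
  ci <- as.matrix(se[, c("lower", "upper")])
  rownames(ci) <- se$parameter
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Likelihood ratio test of the homogeneous against the non-homogeneous model
#'
#' Accepts either two nested \code{nh_fit} objects fitted to the same cohort
#' or the two \code{-2 log L} values directly (in which case \code{df} must
#' be given). The statistic is the deviance difference, referred to a
#' chi-squared distribution with \code{df} equal to the difference in free
#' parameter counts.
#'
#' @param fit_hom Homogeneous fit, or its \code{-2 log L}.
#' @param fit_nonhom Non-homogeneous fit, or its \code{-2 log L}.
#' @param df Degrees of freedom, required when raw deviances are supplied.
#' @return An object of class \code{htest}.
#' @examples
#' likelihood_ratio_test(198878, 198024, df = 3)
#' @export
likelihood_ratio_test <- function(fit_hom, fit_nonhom, df = NULL) {
  if (inherits(fit_hom, "nh_fit") && inherits(fit_nonhom, "nh_fit")) {
    if (fit_hom$n_women != fit_nonhom$n_women)
      stop("the two fits are not on the same cohort")
    m2_h <- fit_hom$minus2loglik
    m2_n <- fit_nonhom$minus2loglik
    if (is.null(df)) df <- fit_nonhom$n_free - fit_hom$n_free
  } else {
    m2_h <- as.numeric(fit_hom)
    m2_n <- as.numeric(fit_nonhom)
    if (is.null(df)) stop("`df` is required when raw -2logL values are given")
  }
  stat <- m2_h - m2_n
  if (stat < 0)
    stop("negative likelihood ratio statistic: the richer model fits worse, ",
         "indicating a failed optimization")
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  structure(list(statistic = c(`chi-squared` = stat),
                 parameter = c(df = df), p.value = p,
                 method = paste("Likelihood ratio test,",
                                "homogeneous vs non-homogeneous model"),
                 data.name = "screening cohort deviances"),
            class = "htest")
}
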