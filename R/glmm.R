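#' Specify a dyadic mixed model
#'
#' The models regress a dyad-level response (an association index, or a
#' hurdle part of one) on fixed effects of dyad sex type, group, their
#' interaction, maternal kinship and age difference, with random
#' intercepts for both members of the dyad. The beta family is
#' parameterized by mean `mu = inverse-logit(eta)` and precision `phi`:
#' `f(y; mu, phi) = Gamma(phi) / (Gamma(mu*phi) Gamma((1-mu)*phi)) *
#' y^(mu*phi-1) (1-y)^((1-mu)*phi-1)`.
#'
#' @param response name of the response column.
#' @param family `"beta"` (logit link, open-interval response) or
#'   `"binomial"` (logit link, 0/1 response).
#' @param fixed one-sided formula of fixed effects; the default is the
#'   full model `~ sex_type * group_id + kin + age_diff`.
#' @param random `"both"` for crossed member-A/member-B intercepts with
#'   role-specific variances, `"none"` for a fixed-effects-only fit.
#' @param shared_variance if `TRUE`, constrain the two role variances to
#'   be equal (single-variance alternative to role-specific intercepts).
#' @return a `model_spec`.
#' @export
model_spec <- function(response,
                       family = c("beta", "binomial"),
                       fixed = ~ sex_type * group_id + kin + age_diff,
                       random = c("both", "none"),
                       shared_variance = FALSE) {
  family <- match.arg(family)
  random <- match.arg(random)
  tl <- attr(stats::terms(fixed), "term.labels")
  inter <- grep(":", tl, value = TRUE)
  for (tt in inter) {
    mains <- strsplit(tt, ":", fixed = TRUE)[[1]]
    if (!all(mains %in% tl)) {
      stop_dyadnet("model", "interaction %s lacks its main effects", tt)
    }
  }
  structure(list(response = response, family = family, fixed = fixed,
                 random = random, shared_variance = shared_variance),
            class = "model_spec")
}

#' Compress proportions off the unit boundary
#'
#' The beta family is supported on the open interval (0,1); observed
#' indices can sit exactly on 0 or 1. The standard compression
#' `y' = (y*(n-1) + 0.5) / n` pulls every value towards 1/2 by half an
#' observation's worth, preserving order.
#'
#' @param values numeric vector in `[0, 1]`.
#' @param n sample size used for the compression (default
#'   `length(values)`); must be at least 2.
#' @return values in (0, 1).
#' @export
squeeze_unit_interval <- function(values, n = length(values)) {
  if (n < 2) stop_dyadnet("model", "squeeze requires n >= 2")
  (values * (n - 1) + 0.5) / n
}

# Prepare model inputs shared by the direct fit and the permutation
# refits: response, design, role indices and factor metadata.
prep_glmm_data <- function(data, spec) {
  d <- as.data.frame(data)
  if (!spec$response %in% names(d)) {
    stop_dyadnet("model", "response column %s not found", spec$response)
  }
  d$sex_type <- factor(d$sex_type, levels = c("FF", "MF", "MM"))
  d$group_id <- factor(d$group_id)
  d$kin <- as.numeric(d$kin)
  y <- as.numeric(d[[spec$response]])
  squeeze_applied <- FALSE
  if (spec$family == "beta") {
    if (any(y < 0 | y > 1)) {
      stop_dyadnet("model", "beta response outside [0,1]")
    }
    if (any(y <= 0 | y >= 1)) {
      y <- squeeze_unit_interval(y)
      squeeze_applied <- TRUE
    }
  } else {
    if (!all(y %in% c(0, 1))) {
      stop_dyadnet("model", "binomial response must be 0/1")
    }
  }
  mf <- stats::model.frame(spec$fixed, d)
  X <- stats::model.matrix(spec$fixed, mf)
  # scale non-constant columns to unit SD for optimizer conditioning;
  # estimates and vcov are mapped back to the original scale after fitting
  col_scale <- apply(X, 2, stats::sd)
  col_scale[col_scale == 0 | !is.finite(col_scale)] <- 1
  X_fit <- sweep(X, 2, col_scale, "/")
  ids <- sort(unique(c(d$member_a, d$member_b)))
  list(y = y, X = X_fit, col_scale = col_scale, colnames_X = colnames(X),
       ia = match(d$member_a, ids) - 1L,
       ib = match(d$member_b, ids) - 1L, ids = ids,
       terms = stats::terms(mf), xlevels = stats::.getXlevels(stats::terms(mf), mf),
       mean_age_diff = mean(d$age_diff),
       group_levels = levels(d$group_id),
       squeeze_applied = squeeze_applied, n_obs = length(y))
}

# Closure over the compiled Laplace objective. The returned object
# mimics the (fn, gr, par) optimizer interface; fn/gr at the same theta
# share one evaluation, the inner mode is warm-started across calls, and
# set_y() swaps the response in place for permutation refits. With
# shared_variance a single log_sigma parameter drives both role
# variances (its gradient is the sum of the two role gradients).
make_laplace_obj <- function(prep, spec) {
  family_code <- if (spec$family == "beta") 0L else 1L
  use_re <- spec$random == "both"
  shared <- use_re && spec$shared_variance
  p <- ncol(prep$X)
  m <- length(prep$ids)
  par <- rep(0, p)
  names(par) <- rep("beta", p)
  if (spec$family == "beta") par <- c(par, log_phi = 1)
  if (use_re) {
    par <- c(par, stats::setNames(rep(-1, if (shared) 1 else 2),
                                  rep("log_sigma", if (shared) 1 else 2)))
  }
  env <- new.env(parent = emptyenv())
  env$y <- prep$y
  env$u <- numeric(0)
  env$last_theta <- NULL
  env$last <- NULL
  X <- prep$X; ia <- prep$ia; ib <- prep$ib
  expand <- function(theta) {
    if (shared) c(theta, theta[length(theta)]) else theta
  }
  evaluate <- function(theta) {
    r <- .dyad_glmm_eval(expand(theta), env$y, X, ia, ib, family_code,
                         use_re, m, env$u, TRUE)
    if (length(r$u)) env$u <- as.numeric(r$u)
    g <- as.numeric(r$grad)
    if (shared) {
      k <- length(g)
      g <- c(g[seq_len(k - 2)], g[k - 1] + g[k])
    }
    env$last_theta <- theta
    env$last <- list(nll = as.numeric(r$nll), grad = g)
    env$last
  }
  list(
    par = par,
    # fn skips the gradient machinery (line-search probes dominate the
    # optimizer's evaluation count); gr computes both and caches
    fn = function(theta) {
      if (identical(theta, env$last_theta)) return(env$last$nll)
      r <- .dyad_glmm_eval(expand(theta), env$y, X, ia, ib, family_code,
                           use_re, m, env$u, FALSE)
      if (length(r$u)) env$u <- as.numeric(r$u)
      as.numeric(r$nll)
    },
    gr = function(theta) {
      if (!identical(theta, env$last_theta)) evaluate(theta)
      env$last$grad
    },
    set_y = function(newy) {
      env$y <- as.numeric(newy)
      env$last_theta <- NULL
      invisible(NULL)
    },
    env = env
  )
}

# Lower box bounds: keep log_sigma away from -Inf (variance MLEs at the
# boundary stall gradient-based stopping); bound-active coordinates are
# excluded from the gradient convergence check.
lower_bounds <- function(par) {
  lw <- rep(-Inf, length(par))
  lw[names(par) == "log_sigma"] <- log(1e-3)
  lw
}

# Upper bounds keep the optimizer out of degenerate territory (an SD of
# 20 or a precision of e^12 on the logit scale is already far beyond any
# interpretable fit).
upper_bounds <- function(par) {
  up <- rep(Inf, length(par))
  up[names(par) == "log_sigma"] <- log(20)
  up[names(par) == "log_phi"] <- 12
  up
}

grad_converged <- function(obj, opt, lower, grad_tol) {
  g <- try(obj$gr(opt$par), silent = TRUE)
  if (inherits(g, "try-error") || !all(is.finite(g))) return(FALSE)
  free <- opt$par > lower + 1e-8 & opt$par < upper_bounds(opt$par) - 1e-8
  max(abs(as.numeric(g)[free])) < grad_tol
}

# Scale-invariant convergence fallback: the Newton decrement
# g' H^-1 g / 2 estimates the log-likelihood still recoverable from the
# current point. An absolute gradient threshold does not scale with the
# data (a |logLik| ~ 2000 fit stalls at gradients ~1e-3 that are
# numerically immaterial); a decrement below `tol` certifies the fit to
# within that likelihood resolution.
newton_decrement_ok <- function(obj, opt, lower, tol = 1e-6) {
  g <- try(obj$gr(opt$par), silent = TRUE)
  if (inherits(g, "try-error") || !all(is.finite(g))) return(FALSE)
  free <- opt$par > lower + 1e-8 & opt$par < upper_bounds(opt$par) - 1e-8
  H <- try(num_hessian(obj$gr, opt$par), silent = TRUE)
  if (inherits(H, "try-error")) return(FALSE)
  gf <- as.numeric(g)[free]
  dec <- try(0.5 * drop(crossprod(gf, solve(H[free, free, drop = FALSE],
                                            gf))),
             silent = TRUE)
  !inherits(dec, "try-error") && is.finite(dec) && abs(dec) < tol
}

optimize_obj <- function(obj, start = NULL, restarts = 5, seed = 1,
                         rel_tol = 1e-10, grad_tol = 1e-4) {
  par0 <- if (is.null(start)) obj$par else start
  lw <- lower_bounds(obj$par)
  up <- upper_bounds(obj$par)
  best <- NULL
  converged <- FALSE
  for (k in 0:restarts) {
    par_try <- par0
    if (k > 0) {
      set.seed(seed * 1000L + k)
      par_try <- pmin(pmax(par0 + stats::rnorm(length(par0), 0, 0.5), lw), up)
    }
    opt <- try(stats::nlminb(par_try, obj$fn, obj$gr, lower = lw,
                             upper = up,
                             control = list(rel.tol = rel_tol,
                                            iter.max = 1000)),
               silent = TRUE)
    if (inherits(opt, "try-error") || !is.finite(opt$objective)) next
    ok <- grad_converged(obj, opt, lw, grad_tol)
    if (!ok) {  # one polishing pass often settles the tail iterations
      opt2 <- try(stats::nlminb(opt$par, obj$fn, obj$gr, lower = lw,
                                upper = up,
                                control = list(rel.tol = rel_tol,
                                               iter.max = 1000)),
                  silent = TRUE)
      if (!inherits(opt2, "try-error") && is.finite(opt2$objective) &&
          opt2$objective <= opt$objective + 1e-10) {
        opt <- opt2
        ok <- grad_converged(obj, opt, lw, grad_tol)
      }
      if (!ok) ok <- newton_decrement_ok(obj, opt, lw)
    }
    better <- is.null(best) || opt$objective < best$objective - 1e-8
    tied_ok <- ok && !converged && !is.null(best) &&
      opt$objective < best$objective + 1e-6
    if (better || tied_ok) {
      best <- opt
      converged <- ok
    }
    if (converged) break
  }
  if (is.null(best)) {
    return(list(opt = NULL, converged = FALSE))
  }
  list(opt = best, converged = converged)
}

num_hessian <- function(gr, par, h = 1e-4) {
  k <- length(par)
  H <- matrix(NA_real_, k, k)
  for (j in seq_len(k)) {
    hj <- h * max(1, abs(par[j]))
    e <- rep(0, k); e[j] <- hj
    H[, j] <- (gr(par + e) - gr(par - e)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Fit a dyadic beta or binomial GLMM
#'
#' Maximizes the marginal likelihood with additive random intercepts
#' `u_a + u_b` over the two member roles, each `Normal(0, sigma^2)` with
#' role-specific variances, integrated out by the Laplace approximation
#' (TMB). Boundary beta responses are compressed off the unit interval
#' (see [squeeze_unit_interval()]) with a logged note. Non-convergence
#' after up to `restarts` jittered restarts is reported via
#' `converged = FALSE`, never silently.
#'
#' @param data a `dyad_table` (with the response column present) — e.g.
#'   from [build_dyad_table()] or [hurdle_split()].
#' @param spec a [model_spec()].
#' @param start optional named start vector on the optimizer scale.
#' @param restarts maximum jittered restarts on non-convergence.
#' @param seed seed for the deterministic restart jitter.
#' @return a `glmm_fit`: coefficient table with standard errors (logit
#'   scale), `phi` (beta precision), `sigma2_a`/`sigma2_b`
#'   (random-intercept variances), `loglik`, `deviance`, `vcov_fixed`,
#'   `converged`, plus the model metadata needed for contrasts.
#' @export
fit_dyad_glmm <- function(data, spec, start = NULL, restarts = 5, seed = 1) {
  prep <- prep_glmm_data(data, spec)
  obj <- make_laplace_obj(prep, spec)
  res <- optimize_obj(obj, start = start, restarts = restarts, seed = seed)
  if (is.null(res$opt)) {
    stop_dyadnet("model", "optimizer failed to return a finite objective")
  }
  opt <- res$opt
  p <- ncol(prep$X)
  # back-transform from the unit-SD design used for optimization
  est <- opt$par[names(opt$par) == "beta"] / prep$col_scale
  names(est) <- prep$colnames_X
  Vth <- try({
    Hth <- num_hessian(obj$gr, opt$par)
    solve(Hth)
  }, silent = TRUE)
  if (!inherits(Vth, "try-error") && all(is.finite(diag(Vth)))) {
    bidx <- which(names(opt$par) == "beta")
    vcov_fixed <- Vth[bidx, bidx, drop = FALSE] / tcrossprod(prep$col_scale)
    dimnames(vcov_fixed) <- list(prep$colnames_X, prep$colnames_X)
    se <- sqrt(pmax(diag(vcov_fixed), 0))
  } else {
    vcov_fixed <- matrix(NA_real_, p, p,
                         dimnames = list(prep$colnames_X, prep$colnames_X))
    se <- rep(NA_real_, p)
  }
  loglik <- -opt$objective
  sig <- exp(opt$par[names(opt$par) == "log_sigma"])
  if (spec$random == "none") sig <- c(0, 0)
  if (spec$shared_variance && length(sig) == 1L) sig <- rep(sig, 2)
  phi <- if (spec$family == "beta") {
    unname(exp(opt$par[names(opt$par) == "log_phi"]))
  } else NA_real_
  fit <- list(
    spec = spec,
    coefficients = data.frame(term = prep$colnames_X, estimate = unname(est),
                              se = se, statistic = unname(est) / se,
                              stringsAsFactors = FALSE),
    beta_hat = est, phi_hat = phi,
    sigma2_a = unname(sig[1])^2, sigma2_b = unname(sig[2])^2,
    loglik = loglik, deviance = -2 * loglik, n_obs = prep$n_obs,
    converged = res$converged, vcov_fixed = vcov_fixed,
    squeeze_applied = prep$squeeze_applied,
    terms = prep$terms, xlevels = prep$xlevels,
    mean_age_diff = prep$mean_age_diff, group_levels = prep$group_levels,
    opt = opt, prep = prep
  )
  class(fit) <- "glmm_fit"
  if (!res$converged) {
    warn_dyadnet("model", "GLMM did not converge (response %s)",
                 spec$response)
  }
  fit
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> %s ~ %s | family %s, n = %d, logLik = %.3f%s\n",
              x$spec$response, deparse(x$spec$fixed[[2]]), x$spec$family,
              x$n_obs, x$loglik,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (x$spec$family == "beta") cat(sprintf("  phi = %.3f,", x$phi_hat))
  cat(sprintf("  sigma2_a = %.4f, sigma2_b = %.4f\n", x$sigma2_a, x$sigma2_b))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' `chi2 = deviance(reduced) - deviance(full)`, with degrees of freedom
#' equal to the difference in fixed-parameter count (2 for dropping a
#' 3-level by 2-level interaction) and an analytic chi-square upper-tail
#' p value. The datastream-permutation p value for the same comparison
#' comes from [run_permutation_test()].
#'
#' @param full,reduced `glmm_fit` objects with nested fixed structures.
#' @return an `lrt_result` with `chi2`, `df`, `p_analytic`.
#' @export
likelihood_ratio <- function(full, reduced) {
  full_terms <- colnames(full$vcov_fixed)
  red_terms <- colnames(reduced$vcov_fixed)
  if (!all(red_terms %in% full_terms)) {
    stop_dyadnet("model", "models are not nested")
  }
  chi2 <- reduced$deviance - full$deviance
  if (chi2 < -1e-6) {
    stop_dyadnet("model",
                 "negative LRT statistic (%.3g): convergence failure", chi2)
  }
  chi2 <- max(chi2, 0)
  df <- length(full_terms) - length(red_terms)
  p <- if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else 1
  structure(list(chi2 = chi2, df = df, p_analytic = p), class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("LRT: chi2 = %.3f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p_analytic))
  invisible(x)
}

#' Between-group contrasts per dyad sex type
#'
#' For each sex type, the estimated marginal difference between the two
#' groups on the link scale, holding kinship at 0 and age difference at
#' its sample mean (emmeans-style). Standard errors come from the fixed-
#' effect covariance via the delta rule; p values use the two-sided
#' normal approximation.
#'
#' @param fit a `glmm_fit` whose fixed structure contains the
#'   `sex_type:group_id` interaction.
#' @return a data frame with one row per sex type: `estimate`
#'   (first group minus second), `se`, `statistic`, `p`.
#' @export
group_contrasts <- function(fit) {
  tl <- attr(fit$terms, "term.labels")
  if (!any(grepl("sex_type:group_id|group_id:sex_type", tl))) {
    stop_dyadnet("model", "fit has no sex_type:group_id interaction")
  }
  if (length(fit$group_levels) != 2L) {
    stop_dyadnet("model", "group contrasts require exactly 2 groups")
  }
  sex_levels <- fit$xlevels$sex_type %||% c("FF", "MF", "MM")
  tt <- stats::delete.response(fit$terms)
  rows <- lapply(sex_levels, function(s) {
    nd <- data.frame(sex_type = factor(s, levels = sex_levels),
                     group_id = factor(fit$group_levels,
                                       levels = fit$group_levels),
                     kin = 0, age_diff = fit$mean_age_diff)
    mm <- stats::model.matrix(tt, stats::model.frame(tt, nd,
                                                     xlev = fit$xlevels))
    cvec <- mm[1, ] - mm[2, ]
    est <- sum(cvec * fit$beta_hat)
    se <- sqrt(drop(t(cvec) %*% fit$vcov_fixed %*% cvec))
    data.frame(sex_type = s, estimate = est, se = se,
               statistic = est / se,
               p = 2 * stats::pnorm(-abs(est / se)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- fit$group_levels
  out
}
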