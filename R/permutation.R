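#' Permute one day's dyadic association events
#'
#' Reassigns the day's associations uniformly at random across the dyads
#' that could have been observed that day (at least one member
#' identified), retaining the original number of associations for the
#' day. The identified sets — and hence every simple-ratio denominator —
#' are untouched.
#'
#' @param events integer vector of dyad indices that scored an event.
#' @param eligible integer vector of dyad indices eligible that day.
#' @return an integer vector of the same length as `events`, drawn
#'   without replacement from `eligible`. Uses the current RNG state.
#' @export
permute_day <- function(events, eligible) {
  n_ev <- length(events)
  if (n_ev > length(eligible)) {
    stop_dyadnet("permutation",
                 "day has more events (%d) than eligible dyads (%d)",
                 n_ev, length(eligible))
  }
  if (n_ev == 0L) return(integer())
  if (n_ev == length(eligible)) return(sort(eligible))
  sort(eligible[sample.int(length(eligible), n_ev)])
}

# Degree-preserving alternative: checkerboard swaps that keep each
# individual's per-day event count. Offered behind the `scheme` flag of
# run_permutation_test; not the default reading of day-level permutation.
permute_day_degree <- function(events, stream, n_swaps = 10L * length(events)) {
  if (length(events) < 2L) return(events)
  pa <- stream$pa[events]; pb <- stream$pb[events]
  n <- length(stream$ids)
  key <- function(a, b) pmin(a, b) * (n + 1L) + pmax(a, b)
  kidx <- matrix(0L, n, n)
  kk <- cbind(stream$pa, stream$pb)
  kidx[kk] <- seq_len(nrow(stream$dyads))
  kidx[kk[, 2:1]] <- seq_len(nrow(stream$dyads))
  present <- new.env(hash = TRUE)
  for (k in seq_along(pa)) assign(as.character(key(pa[k], pb[k])), TRUE, present)
  for (s in seq_len(n_swaps)) {
    ij <- sample.int(length(pa), 2L)
    i <- ij[1]; j <- ij[2]
    a1 <- pa[i]; b1 <- pb[i]; a2 <- pa[j]; b2 <- pb[j]
    # swap partners: (a1,b2) and (a2,b1)
    if (a1 == b2 || a2 == b1) next
    k1 <- key(a1, b2); k2 <- key(a2, b1)
    if (exists(as.character(k1), present) || exists(as.character(k2), present)) next
    rm(list = as.character(c(key(a1, b1), key(a2, b2))), envir = present)
    assign(as.character(k1), TRUE, present)
    assign(as.character(k2), TRUE, present)
    pb[i] <- b2; pb[j] <- b1
  }
  sort(kidx[cbind(pa, pb)])
}

# Eligible dyads per day: at least one member identified.
eligible_by_day <- function(stream) {
  lapply(seq_along(stream$days), function(d) {
    seen <- stream$identified[d, ]
    which(seen[stream$pa] | seen[stream$pb])
  })
}

# Assemble the model frame for one measure/response type from per-group
# streams and per-group event counts x (list over groups).
perm_model_frame <- function(streams, x_list, measure, response_type) {
  parts <- lapply(seq_along(streams), function(gi) {
    st <- streams[[gi]]
    tab <- st$dyads
    den <- tally_all(st, measure)[, "denominator"]
    tab$den <- den
    tab$x <- x_list[[gi]]
    tab
  })
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  tab$sri <- ifelse(tab$den > 0, tab$x / tab$den, 0)
  if (response_type == "sri") {
    tab$y <- tab$sri
  } else if (response_type == "occurrence") {
    tab$y <- as.integer(tab$sri > 0)
  } else {
    tab <- tab[tab$sri > 0, , drop = FALSE]
    tab$y <- tab$sri
  }
  tab
}

#' Datastream permutation test of the group-by-dyad-sex interaction
#'
#' Runs the full prenetwork-permutation inference for one association
#' measure and hurdle part: binarize the focal stream per day, fit the
#' full (`sex_type * group_id`) and reduced (main effects only) GLMMs,
#' then for each of `n_perm` iterations independently permute every day's
#' associations (per group), rebuild the simple-ratio responses, refit
#' both models and record the deviance difference. The permutation p
#' value is `P_rand = sum(observed_delta <= null_delta) / n_valid`:
#' the proportion of permuted deviance differences at least as large as
#' the observed one.
#'
#' Non-converged permuted fits are dropped and counted (`n_failed`), not
#' retried; a warning flag is set when more than 10% fail.
#'
#' @param records a `focal_records` table covering the analysis groups.
#' @param roster the `roster`; excluded individuals are dropped.
#' @param measure `"party10m"`, `"direct1m"` or `"grooming"`.
#' @param response_type `"sri"` (single beta model on the index),
#'   `"occurrence"` (binomial hurdle part) or `"magnitude"` (beta on the
#'   positive indices; the row set changes per permutation).
#' @param n_perm number of permutations (study default 1000).
#' @param seed integer seed; the full null sequence is reproducible.
#' @param scheme `"uniform-day"` (default: uniform reassignment given the
#'   day's event count) or `"degree-preserving"` (checkerboard swaps that
#'   also keep per-individual daily event counts).
#' @param fixed_full,fixed_reduced fixed-effect formulas of the compared
#'   models.
#' @param identified_rule see [binarize_daily()].
#' @param shared_variance see [model_spec()].
#' @return a `permutation_result` with `observed_delta`, `null_deltas`,
#'   `p_rand`, `n_failed`, `n_perm`, `seed` and the observed model
#'   log-likelihoods.
#' @export
run_permutation_test <- function(records, roster, measure = "party10m",
                                 response_type = c("sri", "occurrence",
                                                   "magnitude"),
                                 n_perm = 1000, seed = 1,
                                 scheme = c("uniform-day", "degree-preserving"),
                                 fixed_full = ~ sex_type * group_id + kin + age_diff,
                                 fixed_reduced = ~ sex_type + group_id + kin + age_diff,
                                 identified_rule = "inclusive",
                                 shared_variance = FALSE) {
  response_type <- match.arg(response_type)
  scheme <- match.arg(scheme)
  family <- if (response_type == "occurrence") "binomial" else "beta"
  groups <- unique(roster$group_id[!roster$excluded])
  streams <- lapply(groups, function(g) {
    binarize_daily(records, active_roster(roster, g), "all",
                   identified_rule = identified_rule)
  })
  elig <- lapply(streams, eligible_by_day)
  obs_x <- lapply(streams, function(st) {
    tally_all(st, measure)[, "x"]
  })
  spec_full <- model_spec("y", family = family, fixed = fixed_full,
                          shared_variance = shared_variance)
  spec_red <- model_spec("y", family = family, fixed = fixed_reduced,
                         shared_variance = shared_variance)

  obs_tab <- perm_model_frame(streams, obs_x, measure, response_type)
  fixed_rows <- response_type != "magnitude"
  dens <- unlist(lapply(streams, function(st) {
    tally_all(st, measure)[, "denominator"]
  }), use.names = FALSE)

  fit_pair_cold <- function(tab) {
    pf <- prep_glmm_data(tab, spec_full)
    pr <- prep_glmm_data(tab, spec_red)
    of <- make_laplace_obj(pf, spec_full)
    or <- make_laplace_obj(pr, spec_red)
    list(pf = pf, pr = pr, of = of, or = or)
  }

  objs <- fit_pair_cold(obs_tab)
  lw_f <- lower_bounds(objs$of$par)
  lw_r <- lower_bounds(objs$or$par)
  res_f <- optimize_obj(objs$of, restarts = 2, seed = seed)
  res_r <- optimize_obj(objs$or, restarts = 2, seed = seed)
  if (is.null(res_f$opt) || is.null(res_r$opt)) {
    stop_dyadnet("permutation", "observed fits failed")
  }
  o_full <- res_f$opt
  o_red <- res_r$opt
  if (!res_f$converged || !res_r$converged) {
    warn_dyadnet("permutation", "observed fits not cleanly converged")
  }
  # curvature-derived parameter scaling: the outer Hessian barely moves
  # across permutations, so one Hessian at the observed optimum makes
  # every warm refit converge in a fraction of the iterations
  hess_scale <- function(obj, opt) {
    sc <- try(sqrt(pmax(diag(num_hessian(obj$gr, opt$par)), 1e-4)),
              silent = TRUE)
    if (inherits(sc, "try-error") || !all(is.finite(sc))) {
      rep(1, length(opt$par))
    } else sc
  }
  sc_f <- hess_scale(objs$of, o_full)
  sc_r <- hess_scale(objs$or, o_red)
  observed_delta <- 2 * (o_red$objective - o_full$objective)

  set.seed(seed)
  null_deltas <- rep(NA_real_, n_perm)
  n_failed <- 0L
  start_f <- o_full$par
  start_r <- o_red$par
  ctl_perm <- list(rel.tol = 1e-9, iter.max = 500)
  # practical convergence for permuted refits: gradient below 0.01 on the
  # standardized design scale (deviance error is second order, far below
  # the resolution that matters for the null distribution)
  perm_grad_tol <- 0.01
  # a refit counts as converged if the free-coordinate gradient is small
  # or the diagonal Newton decrement (via the curvature scale) certifies
  # the remaining likelihood improvement as negligible
  perm_converged <- function(obj, o, lower, scale) {
    g <- try(obj$gr(o$par), silent = TRUE)
    if (inherits(g, "try-error") || !all(is.finite(g))) return(FALSE)
    free <- o$par > lower + 1e-8 & o$par < upper_bounds(o$par) - 1e-8
    gf <- as.numeric(g)[free]
    if (max(abs(gf)) < perm_grad_tol) return(TRUE)
    if (length(scale) == length(o$par)) {
      dec <- 0.5 * sum((gf / scale[free])^2)
      return(is.finite(dec) && dec < 1e-6)
    }
    FALSE
  }
  refit <- function(obj, start, lower, scale = 1) {
    up <- upper_bounds(start)
    o <- try(stats::nlminb(start, obj$fn, obj$gr, lower = lower, upper = up,
                           scale = scale, control = ctl_perm), silent = TRUE)
    if (inherits(o, "try-error") || !is.finite(o$objective)) return(NULL)
    if (!perm_converged(obj, o, lower, scale)) {
      o2 <- try(stats::nlminb(o$par, obj$fn, obj$gr, lower = lower, upper = up,
                              scale = scale, control = ctl_perm), silent = TRUE)
      if (!inherits(o2, "try-error") && is.finite(o2$objective)) o <- o2
      if (!perm_converged(obj, o, lower, scale)) return(NULL)
    }
    o
  }
  for (it in seq_len(n_perm)) {
    x_list <- vector("list", length(streams))
    for (gi in seq_along(streams)) {
      st <- streams[[gi]]
      K <- nrow(st$dyads)
      ev_all <- integer()
      for (d in seq_along(st$days)) {
        ev <- st$events[[measure]][[d]]
        new_ev <- if (scheme == "uniform-day") {
          permute_day(ev, elig[[gi]][[d]])
        } else {
          permute_day_degree(ev, st)
        }
        ev_all <- c(ev_all, new_ev)
      }
      x_list[[gi]] <- tabulate(ev_all, nbins = K)
    }
    ok <- TRUE
    if (fixed_rows) {
      # row set is fixed: only the response changes, so skip the frame
      # rebuild and update the taped objectives in place
      x_all <- unlist(x_list, use.names = FALSE)
      yv <- if (response_type == "sri") {
        ifelse(dens > 0, x_all / dens, 0)
      } else {
        as.numeric(x_all > 0)
      }
      newy <- prep_response(yv, family)
      objs$of$set_y(newy)
      objs$or$set_y(newy)
      o1 <- refit(objs$of, start_f, lw_f, sc_f)
      o2 <- refit(objs$or, start_r, lw_r, sc_r)
      ok <- !is.null(o1) && !is.null(o2)
      if (ok) {
        null_deltas[it] <- 2 * (o2$objective - o1$objective)
        start_f <- o1$par
        start_r <- o2$par
      }
    } else {
      tab <- perm_model_frame(streams, x_list, measure, response_type)
      ok <- nrow(tab) >= length(attr(stats::terms(fixed_full), "term.labels")) + 2
      if (ok) {
        po <- try(fit_pair_cold(tab), silent = TRUE)
        if (inherits(po, "try-error")) {
          ok <- FALSE
        } else {
          o1 <- refit(po$of, po$of$par, lower_bounds(po$of$par))
          o2 <- refit(po$or, po$or$par, lower_bounds(po$or$par))
          ok <- !is.null(o1) && !is.null(o2)
          if (ok) null_deltas[it] <- 2 * (o2$objective - o1$objective)
        }
      }
    }
    if (!ok) n_failed <- n_failed + 1L
  }
  null_deltas <- null_deltas[!is.na(null_deltas)]
  p_rand <- if (length(null_deltas)) {
    sum(observed_delta <= null_deltas) / length(null_deltas)
  } else NA_real_
  out <- list(measure = measure, response_type = response_type,
              scheme = scheme, n_perm = as.integer(n_perm),
              observed_delta = observed_delta,
              null_deltas = null_deltas, p_rand = p_rand,
              n_failed = n_failed, seed = as.integer(seed),
              loglik_full = -o_full$objective,
              loglik_reduced = -o_red$objective,
              high_failure = n_failed > 0.1 * n_perm)
  class(out) <- "permutation_result"
  if (out$high_failure) {
    warn_dyadnet("permutation", "%d/%d permuted fits failed to converge",
                 n_failed, n_perm)
  }
  out
}

# Response-side preprocessing matching prep_glmm_data (squeeze for beta).
prep_response <- function(y, family) {
  y <- as.numeric(y)
  if (family == "beta" && any(y <= 0 | y >= 1)) {
    y <- squeeze_unit_interval(y)
  }
  y
}

#' Format a permutation p value
#'
#' Zero counts are reported as a bound, never as exactly 0.
#'
#' @param x a `permutation_result`.
#' @return character scalar, e.g. `"0.012"` or `"< 0.001"`.
#' @export
format_p_rand <- function(x) {
  n <- length(x$null_deltas)
  if (!n) return("NA")
  if (x$p_rand == 0) sprintf("< %.3g", 1 / n) else sprintf("%.3g", x$p_rand)
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s / %s (%s)\n  observed delta-deviance = %.3f, n_perm = %d (%d failed)\n  P_rand = %s\n",
    x$measure, x$response_type, x$scheme, x$observed_delta, x$n_perm,
    x$n_failed, format_p_rand(x)))
  if (x$high_failure) cat("  WARNING: >10% of permuted fits failed\n")
  invisible(x)
}
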