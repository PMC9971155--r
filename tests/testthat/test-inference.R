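# shared fixture: moderate synthetic study reused across inference tests
sim_inf <- simulate_study(test_config(n_per_sex = 4, n_days = 20, seed = 42))
dt_inf <- build_dyad_table(sim_inf$records, sim_inf$roster)
dt_inf$y <- dt_inf$sri_party

test_that("model_spec validates interaction structure and family support", {
  expect_error(model_spec("y", fixed = ~ sex_type:group_id + kin),
               "main effects")
  spec <- model_spec("y", family = "binomial")
  bad <- dt_inf; bad$y <- bad$sri_party  # continuous, not 0/1
  expect_error(fit_dyad_glmm(bad, spec), "0/1")
  specb <- model_spec("bad_y", family = "beta")
  bad2 <- dt_inf; bad2$bad_y <- bad2$sri_party * 2
  expect_error(fit_dyad_glmm(bad2, specb), "outside")
})

test_that("unit-interval squeeze matches its closed form and fixed point", {
  expect_equal(squeeze_unit_interval(0, n = 100), 0.005)
  expect_equal(squeeze_unit_interval(1, n = 100), 0.995)
  expect_equal(squeeze_unit_interval(0.5, n = 17), 0.5)
  y <- c(0, 0.2, 0.8, 1)
  expect_equal(order(squeeze_unit_interval(y)), order(y))
  expect_error(squeeze_unit_interval(0.5, n = 1), "n >= 2")
})

test_that("beta density parameterization integrates to one", {
  for (mu in c(0.1, 0.5, 0.85)) {
    for (phi in c(2, 10, 50)) {
      int <- stats::integrate(function(y) {
        stats::dbeta(y, mu * phi, (1 - mu) * phi)
      }, 0, 1)$value
      expect_equal(int, 1, tolerance = 1e-6)
    }
  }
})

test_that("sigma-free fits agree with an independent fixed-effects beta ML", {
  spec <- model_spec("y", family = "beta", random = "none")
  fit <- fit_dyad_glmm(dt_inf, spec)
  y <- squeeze_unit_interval(dt_inf$y)
  X <- model.matrix(~ sex_type * group_id + kin + age_diff,
                    transform(as.data.frame(dt_inf),
                              sex_type = factor(sex_type),
                              group_id = factor(group_id),
                              kin = as.numeric(kin)))
  ora <- oracle_beta_reg(y, X)
  expect_equal(unname(fit$beta_hat), ora$beta, tolerance = 1e-3)
  expect_equal(fit$loglik, ora$loglik, tolerance = 1e-5)
  expect_equal(fit$sigma2_a, 0)
})

test_that("balanced intercept-only binomial data recovers logit(0.5) = 0", {
  d <- dt_inf
  d$occ <- rep(c(0, 1), length.out = nrow(d))
  spec <- model_spec("occ", family = "binomial", fixed = ~ 1,
                     random = "none")
  fit <- fit_dyad_glmm(d, spec)
  expect_equal(unname(fit$beta_hat), 0, tolerance = 1e-6)
})

# 4 individuals, dyads AB/AC/AD/BC observed over `reps` periods, with
# role effects of spread `usd`: 5 active random-effect dimensions, small
# enough that non-adaptive quadrature still resolves the integrand
gh_fixture <- function(reps, usd, seed) {
  set.seed(seed)
  pat_a <- c("A", "A", "A", "B"); pat_b <- c("B", "C", "D", "C")
  u <- stats::setNames(rnorm(4, 0, usd), c("A", "B", "C", "D"))
  ia <- rep(pat_a, reps); ib <- rep(pat_b, reps)
  mu <- plogis(-1 + u[ia] + u[ib])
  data.frame(member_a = ia, member_b = ib, sex_type = "FF",
             group_id = "g1", kin = rep(c(1, 0, 0, 0), reps),
             age_diff = 1,
             y = pmin(pmax(rbeta(length(mu), mu * 12, (1 - mu) * 12),
                           0.01), 0.99),
             yb = rbinom(length(mu), 1, mu))
}

test_that("Laplace log-likelihood is close to dense Gauss-Hermite quadrature", {
  d <- gh_fixture(reps = 3, usd = 0.8, seed = 103)
  spec <- model_spec("y", family = "beta", fixed = ~ kin)
  fit <- fit_dyad_glmm(d, spec)
  prep <- dyadnet:::prep_glmm_data(d, spec)
  gh <- oracle_gh_nll(fit$opt$par, prep$y, prep$X, prep$ia, prep$ib,
                      family = "beta", k = 21)
  expect_lt(abs(-fit$loglik - gh), 0.05)
  # and a binomial instance on the same crossing structure
  specb <- model_spec("yb", family = "binomial", fixed = ~ 1)
  fitb <- fit_dyad_glmm(d, specb)
  prepb <- dyadnet:::prep_glmm_data(d, specb)
  ghb <- oracle_gh_nll(fitb$opt$par, prepb$y, prepb$X, prepb$ia, prepb$ib,
                       family = "binomial", k = 21)
  expect_lt(abs(-fitb$loglik - ghb), 0.05)
})

test_that("fits agree with glmmTMB on estimates, likelihood and variances", {
  skip_if_not_installed("glmmTMB")
  spec <- model_spec("y", family = "beta")
  fit <- fit_dyad_glmm(dt_inf, spec)
  d2 <- as.data.frame(dt_inf)
  d2$ys <- squeeze_unit_interval(d2$y)
  gt <- glmmTMB::glmmTMB(
    ys ~ sex_type * group_id + kin + age_diff + (1 | member_a) + (1 | member_b),
    data = d2, family = glmmTMB::beta_family())
  expect_equal(fit$loglik, as.numeric(stats::logLik(gt)), tolerance = 1e-4)
  expect_equal(unname(fit$beta_hat), unname(glmmTMB::fixef(gt)$cond),
               tolerance = 1e-3)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(stats::vcov(gt)$cond))), tolerance = 1e-3)
  expect_equal(sort(c(fit$sigma2_a, fit$sigma2_b)),
               sort(unname(unlist(glmmTMB::VarCorr(gt)$cond))),
               tolerance = 1e-3)
})

test_that("adding fixed terms never decreases the maximized log-likelihood", {
  ladder <- list(~ 1,
                 ~ sex_type,
                 ~ sex_type + group_id,
                 ~ sex_type + group_id + kin,
                 ~ sex_type + group_id + kin + age_diff,
                 ~ sex_type * group_id + kin + age_diff)
  ll <- vapply(ladder, function(f) {
    fit_dyad_glmm(dt_inf, model_spec("y", family = "beta", fixed = f))$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-4))
})

test_that("likelihood-ratio tests report chi2, df and analytic p correctly", {
  full <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta"))
  red <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta",
                                          fixed = ~ sex_type + group_id +
                                            kin + age_diff))
  lrt <- likelihood_ratio(full, red)
  expect_equal(lrt$df, 2)
  expect_gte(lrt$chi2, 0)
  expect_equal(lrt$p_analytic,
               pchisq(lrt$chi2, 2, lower.tail = FALSE))
  ident <- likelihood_ratio(full, full)
  expect_equal(ident$chi2, 0, tolerance = 1e-8)
  expect_equal(ident$p_analytic, 1)
  other <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta",
                                            fixed = ~ kin))
  # reduced model with terms absent from the "full" one is not nested
  expect_error(likelihood_ratio(other, red), "not nested")
})

test_that("group contrasts match emmeans on an identical glmmTMB fit", {
  skip_if_not_installed("glmmTMB")
  skip_if_not_installed("emmeans")
  fit <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta"))
  ctr <- group_contrasts(fit)
  d2 <- as.data.frame(dt_inf)
  d2$ys <- squeeze_unit_interval(d2$y)
  d2$sex_type <- factor(d2$sex_type)
  d2$group_id <- factor(d2$group_id)
  d2$kin <- as.numeric(d2$kin)  # logical kin trips emmeans' contrasts
  gt <- glmmTMB::glmmTMB(
    ys ~ sex_type * group_id + kin + age_diff + (1 | member_a) + (1 | member_b),
    data = d2, family = glmmTMB::beta_family())
  em <- emmeans::emmeans(gt, ~ group_id | sex_type,
                         at = list(kin = 0, age_diff = mean(d2$age_diff)))
  emc <- as.data.frame(emmeans::contrast(em, "pairwise"))
  expect_equal(ctr$estimate, emc$estimate, tolerance = 1e-3)
  expect_equal(ctr$se, emc$SE, tolerance = 1e-3)
})

test_that("contrasts require the interaction and collapse to the main effect without it", {
  red <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta",
                                          fixed = ~ sex_type + group_id +
                                            kin + age_diff))
  expect_error(group_contrasts(red), "interaction")
  # a fit whose interaction coefficients are exactly zero: contrasts all
  # equal the group main effect
  fit <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta"))
  fit$beta_hat[grep(":", names(fit$beta_hat))] <- 0
  ctr <- group_contrasts(fit)
  expect_equal(ctr$estimate[1], ctr$estimate[2], tolerance = 1e-10)
  expect_equal(ctr$estimate[2], ctr$estimate[3], tolerance = 1e-10)
  expect_equal(abs(ctr$estimate[1]),
               abs(unname(fit$beta_hat["group_idg2"])), tolerance = 1e-10)
})

test_that("a generous kin effect yields a positive, significant kin coefficient", {
  hits <- 0L
  nrep <- 10L
  for (r in seq_len(nrep)) {
    cfg <- generator_config(groups = list(
      list(group_id = "g1", n_males = 4, n_females = 4,
           n_maternal_lines = 3),
      list(group_id = "g2", n_males = 4, n_females = 4,
           n_maternal_lines = 3)),
      n_days = 30, seed = 500 + r, beta_kin = 2, sigma_indiv = 0.3)
    sim <- simulate_study(cfg)
    dt <- build_dyad_table(sim$records, sim$roster)
    dt$y <- dt$sri_party
    full <- suppressWarnings(
      fit_dyad_glmm(dt, model_spec("y", family = "beta",
                                   fixed = ~ sex_type + group_id + kin +
                                     age_diff)))
    nokin <- suppressWarnings(
      fit_dyad_glmm(dt, model_spec("y", family = "beta",
                                   fixed = ~ sex_type + group_id +
                                     age_diff)))
    lrt <- likelihood_ratio(full, nokin)
    if (unname(full$beta_hat["kin"]) > 0 && lrt$p_analytic < 0.05) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / nrep, 0.8)
})

test_that("shared-variance fits constrain the two role variances to be equal", {
  spec <- model_spec("y", family = "beta", shared_variance = TRUE)
  fit <- fit_dyad_glmm(dt_inf, spec)
  expect_equal(fit$sigma2_a, fit$sigma2_b)
  free <- fit_dyad_glmm(dt_inf, model_spec("y", family = "beta"))
  expect_gte(free$loglik, fit$loglik - 1e-6)
})
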