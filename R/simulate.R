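#' Configuration for the synthetic focal-sampling generator
#'
#' The generator emulates the observation process of a two-group
#' focal-sampling study: each day a randomized subset of individuals is
#' sampled as focals, and for each 5-minute focal sample every possible
#' partner joins the focal's 10 m party with probability
#' `inverse-logit(beta0 + beta_sextype_by_group + beta_kin*kin +
#' beta_age*|age difference| + u_i + u_j)`, where the `u` are
#' per-individual gregariousness intercepts drawn once per season from
#' `Normal(0, sigma_indiv^2)`. Partners in the party enter the 1 m circle
#' independently with `p_close_given_party`, and grooming is drawn only
#' from 1 m partners with `p_groom_given_close`, so the three observation
#' streams are strictly nested.
#'
#' Defaults emulate the study conditions the pipeline targets: two
#' chimpanzee groups (11 M + 11 F and 10 M + 29 F), a roughly three-month
#' season (60 observation days) with about 20 focal samples per
#' individual, maternal-kin attraction, and a female-female association
#' surplus confined to the first group.
#'
#' @param groups list of group specs, each a list with `group_id`,
#'   `n_males`, `n_females`, `n_maternal_lines`.
#' @param n_days number of observation days (default 60).
#' @param focals_per_individual target total focal samples per individual
#'   over the season (default 20); per-day focal subsets are sized to hit
#'   it.
#' @param beta0 baseline log-odds of a partner joining the 10 m party in
#'   one focal sample (default -2.5).
#' @param beta_sextype_by_group named list `group_id -> c(FF=, MF=, MM=)`
#'   additive log-odds effects; defaults to a +1 FF effect in the first
#'   group and 0 elsewhere.
#' @param beta_kin log-odds bonus for maternal kin (default 1).
#' @param beta_age log-odds change per year of absolute age difference
#'   (default -0.02).
#' @param sigma_indiv SD of individual gregariousness intercepts
#'   (default 0.5).
#' @param p_close_given_party probability a party member is also within
#'   1 m (default 0.3).
#' @param p_groom_given_close probability a 1 m partner is groomed
#'   (default 0.3).
#' @param age_range uniform age range in years for generated rosters
#'   (default 4-40).
#' @param start_date first observation day.
#' @param seed integer seed; every generator draw derives from it.
#' @return a `generator_config` list.
#' @export
generator_config <- function(groups = list(
                               list(group_id = "g1", n_males = 11,
                                    n_females = 11, n_maternal_lines = 8),
                               list(group_id = "g2", n_males = 10,
                                    n_females = 29, n_maternal_lines = 14)),
                             n_days = 60,
                             focals_per_individual = 20,
                             beta0 = -2.5,
                             beta_sextype_by_group = NULL,
                             beta_kin = 1,
                             beta_age = -0.02,
                             sigma_indiv = 0.5,
                             p_close_given_party = 0.3,
                             p_groom_given_close = 0.3,
                             age_range = c(4, 40),
                             start_date = as.Date("2013-07-01"),
                             seed = 1L) {
  gids <- vapply(groups, `[[`, character(1), "group_id")
  if (is.null(beta_sextype_by_group)) {
    beta_sextype_by_group <- stats::setNames(
      rep(list(c(FF = 0, MF = 0, MM = 0)), length(gids)), gids)
    beta_sextype_by_group[[1]]["FF"] <- 1
  }
  cfg <- list(groups = groups, n_days = as.integer(n_days),
              focals_per_individual = focals_per_individual,
              beta0 = beta0, beta_sextype_by_group = beta_sextype_by_group,
              beta_kin = beta_kin, beta_age = beta_age,
              sigma_indiv = sigma_indiv,
              p_close_given_party = p_close_given_party,
              p_groom_given_close = p_groom_given_close,
              age_range = age_range, start_date = as.Date(start_date),
              seed = as.integer(seed))
  validate_generator_config(cfg)
  class(cfg) <- c("generator_config", "list")
  cfg
}

validate_generator_config <- function(cfg) {
  probs <- c(cfg$p_close_given_party, cfg$p_groom_given_close)
  if (any(probs < 0 | probs > 1)) {
    stop_dyadnet("generator", "probabilities must lie in [0,1]")
  }
  if (cfg$n_days < 1L) stop_dyadnet("generator", "n_days must be >= 1")
  for (g in cfg$groups) {
    n <- g$n_males + g$n_females
    if (n < 2L) stop_dyadnet("generator", "group %s has size < 2", g$group_id)
    if (g$n_maternal_lines > n) {
      stop_dyadnet("generator",
                   "group %s: n_maternal_lines (%d) exceeds group size (%d)",
                   g$group_id, g$n_maternal_lines, n)
    }
    if (!g$group_id %in% names(cfg$beta_sextype_by_group)) {
      stop_dyadnet("generator", "no sex-type effects for group %s", g$group_id)
    }
  }
  invisible(TRUE)
}

#' Zero out all group differences in a generator config
#'
#' Convenience for null (type-I) simulations: sets every sex-type-by-group
#' effect to the across-group mean of that sex type so that no
#' group-by-sex-type interaction remains, leaving everything else as
#' configured.
#'
#' @param cfg a `generator_config`.
#' @return the modified config.
#' @export
null_group_effects <- function(cfg) {
  eff <- cfg$beta_sextype_by_group
  m <- Reduce(`+`, eff) / length(eff)
  cfg$beta_sextype_by_group <- stats::setNames(
    rep(list(m), length(eff)), names(eff))
  cfg
}

#' Generate a synthetic roster
#'
#' Ages are uniform over `cfg$age_range`; maternal lines are founder
#' labels assigned cyclically so that each group has
#' `n_maternal_lines` lines (a line with a single member yields no kin
#' dyads). Deterministic given `cfg$seed`.
#'
#' @param cfg a `generator_config`.
#' @return a `roster` covering all configured groups.
#' @export
generate_roster <- function(cfg) {
  set.seed(cfg$seed)
  rows <- lapply(cfg$groups, function(g) {
    n <- g$n_males + g$n_females
    ids <- sprintf("%s_%02d", toupper(g$group_id), seq_len(n))
    sex <- c(rep("M", g$n_males), rep("F", g$n_females))
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    line <- sprintf("%s_L%02d",
                    toupper(g$group_id),
                    rep_len(seq_len(g$n_maternal_lines), n))
    data.frame(id = ids, sex = sex, age_years = age, group_id = g$group_id,
               maternal_line = line, stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, rows)
  r <- roster(d$id, d$sex, d$age_years, d$group_id, d$maternal_line,
              min_age = 0)
  append_log(r, log_line("INFO", "generator",
                         sprintf("roster seed %d", cfg$seed)))
}

#' True per-sample association probability for a dyad
#'
#' The inverse-logit of the generating linear predictor, exposed so tests
#' can compare realized association frequencies with ground truth.
#'
#' @param dyad one-row slice of a `dyad_table` (or a list with
#'   `sex_type`, `kin`, `age_diff`, `group_id`).
#' @param u_a,u_b the members' gregariousness intercepts.
#' @param cfg a `generator_config`.
#' @return probability in (0,1).
#' @export
true_dyad_probability <- function(dyad, u_a, u_b, cfg) {
  eff <- cfg$beta_sextype_by_group[[dyad$group_id]]
  if (is.null(eff) || !dyad$sex_type %in% names(eff)) {
    stop_dyadnet("generator", "no effect for group %s sex type %s",
                 dyad$group_id, dyad$sex_type)
  }
  eta <- cfg$beta0 + eff[[dyad$sex_type]] + cfg$beta_kin * as.numeric(dyad$kin) +
    cfg$beta_age * dyad$age_diff + u_a + u_b
  inv_logit(eta)
}

#' Generate a synthetic focal-record stream
#'
#' For each day a randomized focal order over a day-specific subset of
#' individuals (sized to reach `focals_per_individual` over the season);
#' for each focal sample partners join the 10 m party independently with
#' their dyad's true probability, 1 m and grooming are nested draws.
#' Individuals not sampled on a day still appear as associates, as in
#' real focal data. Deterministic given `cfg$seed`.
#'
#' @param roster a `roster` from [generate_roster()] (or compatible).
#' @param cfg a `generator_config`.
#' @return a `focal_records` table; the individual intercepts used are
#'   attached as attribute `"u"` (named vector) for parameter-recovery
#'   checks.
#' @export
generate_focal_stream <- function(roster, cfg) {
  set.seed(cfg$seed + 1L)
  u <- stats::setNames(stats::rnorm(nrow(roster), 0, cfg$sigma_indiv),
                       roster$id)
  dates <- cfg$start_date + seq_len(cfg$n_days) - 1L
  out <- vector("list", length(cfg$groups))
  for (gi in seq_along(cfg$groups)) {
    g <- cfg$groups[[gi]]
    r <- roster[roster$group_id == g$group_id, , drop = FALSE]
    r <- r[order(r$id), , drop = FALSE]
    n <- nrow(r)
    dy <- enumerate_dyads(r)
    eff <- cfg$beta_sextype_by_group[[g$group_id]]
    eta <- cfg$beta0 + unname(eff[dy$sex_type]) +
      cfg$beta_kin * as.numeric(dy$kin) + cfg$beta_age * dy$age_diff +
      u[dy$member_a] + u[dy$member_b]
    p_dyad <- inv_logit(eta)
    # dyad index lookup: pair (i<j) of row positions -> dyad row
    kidx <- matrix(0L, n, n)
    cmb <- utils::combn(n, 2L)
    kidx[cbind(cmb[1, ], cmb[2, ])] <- seq_len(ncol(cmb))
    kidx[cbind(cmb[2, ], cmb[1, ])] <- seq_len(ncol(cmb))

    # per-day focal subsets: expected n * focals_per_individual / n_days
    target_per_day <- n * cfg$focals_per_individual / cfg$n_days
    recs <- vector("list", cfg$n_days)
    for (d in seq_len(cfg$n_days)) {
      m <- floor(target_per_day) +
        (stats::runif(1) < (target_per_day - floor(target_per_day)))
      m <- min(n, m)
      if (m == 0L) next
      focal_pos <- sample.int(n, m)  # randomized order, no repeats per day
      w10 <- vector("list", m); w1 <- vector("list", m); gr <- vector("list", m)
      for (s in seq_len(m)) {
        i <- focal_pos[s]
        others <- setdiff(seq_len(n), i)
        p <- p_dyad[kidx[i, others]]
        joined <- others[stats::runif(n - 1L) < p]
        close <- joined[stats::runif(length(joined)) < cfg$p_close_given_party]
        groomed <- close[stats::runif(length(close)) < cfg$p_groom_given_close]
        w10[[s]] <- r$id[joined]; w1[[s]] <- r$id[close]
        gr[[s]] <- r$id[groomed]
      }
      recs[[d]] <- data.frame(
        date = rep(dates[d], m), focal_id = r$id[focal_pos],
        within10m = join_ids(w10), within1m = join_ids(w1),
        grooming = join_ids(gr), stringsAsFactors = FALSE)
    }
    out[[gi]] <- do.call(rbind, recs[!vapply(recs, is.null, logical(1))])
  }
  d <- do.call(rbind, out)
  fr <- focal_records(d$date, d$focal_id, d$within10m, d$within1m,
                      d$grooming, roster = roster)
  attr(fr, "u") <- u
  append_log(fr, log_line("INFO", "generator",
                          sprintf("focal stream seed %d", cfg$seed)))
}

#' Generate a complete synthetic study
#'
#' @param cfg a `generator_config`.
#' @return list with `roster`, `records`, `config`.
#' @export
simulate_study <- function(cfg = generator_config()) {
  r <- generate_roster(cfg)
  rec <- generate_focal_stream(r, cfg)
  list(roster = r, records = rec, config = cfg)
}
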