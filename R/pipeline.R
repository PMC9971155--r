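#' Assemble a pipeline run configuration
#'
#' Exactly one of `input` (paths to a roster and focal-record file) or
#' `generator` (a [generator_config()]) must be supplied. The default
#' model ladder mirrors the standard three-model structure: a single beta
#' model for party co-residence, and binomial occurrence plus beta
#' magnitude hurdle parts for direct (1 m) proximity and grooming.
#'
#' @param input optional list with `roster` and `records` file paths.
#' @param generator optional [generator_config()].
#' @param measures association streams to analyze.
#' @param n_perm permutations per test (0 skips permutation inference).
#' @param seed master seed; per-test permutation seeds derive from it and
#'   are recorded in the manifest.
#' @param out_dir output directory for all artifacts.
#' @param identified_rule see [binarize_daily()].
#' @param scheme permutation scheme, see [run_permutation_test()].
#' @param shared_variance see [model_spec()].
#' @param min_age minimum subject age for loaded rosters.
#' @return a `run_config`.
#' @export
run_config <- function(input = NULL, generator = NULL,
                       measures = c("party10m", "direct1m", "grooming"),
                       n_perm = 1000, seed = 1, out_dir = "dyadnet_run",
                       identified_rule = "inclusive",
                       scheme = "uniform-day",
                       shared_variance = FALSE,
                       min_age = 4) {
  if (is.null(input) == is.null(generator)) {
    stop_dyadnet("pipeline",
                 "exactly one of input or generator must be given")
  }
  cfg <- list(input = input, generator = generator, measures = measures,
              n_perm = as.integer(n_perm), seed = as.integer(seed),
              out_dir = out_dir, identified_rule = identified_rule,
              scheme = scheme, shared_variance = shared_variance,
              min_age = min_age)
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return a `run_config` (reader); `path` invisibly (writer).
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gen <- NULL
  if (!is.null(raw$generator)) {
    g <- raw$generator
    g$beta_sextype_by_group <- lapply(g$beta_sextype_by_group, unlist)
    gen <- do.call(generator_config, g)
  }
  run_config(input = raw$input, generator = gen,
             measures = raw$measures %||% c("party10m", "direct1m", "grooming"),
             n_perm = raw$n_perm %||% 1000, seed = raw$seed %||% 1,
             out_dir = raw$out_dir %||% "dyadnet_run",
             identified_rule = raw$identified_rule %||% "inclusive",
             scheme = raw$scheme %||% "uniform-day",
             shared_variance = isTRUE(raw$shared_variance),
             min_age = raw$min_age %||% 4)
}

#' @rdname load_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  ser <- unclass(config)
  if (!is.null(ser$generator)) {
    ser$generator <- unclass(ser$generator)
    ser$generator$start_date <- as.character(ser$generator$start_date)
    ser$generator$beta_sextype_by_group <-
      lapply(ser$generator$beta_sextype_by_group, as.list)
  }
  yaml::write_yaml(ser, path)
  invisible(path)
}

measure_parts <- function(measure) {
  if (measure == "party10m") "sri" else c("occurrence", "magnitude")
}

sri_column <- function(measure) {
  c(party10m = "sri_party", direct1m = "sri_direct",
    grooming = "sri_groom")[[measure]]
}

write_fit <- function(fit, path) {
  co <- fit$coefficients
  extra <- data.frame(term = c("(phi)", "(sigma2_a)", "(sigma2_b)",
                               "(loglik)", "(converged)"),
                      estimate = c(fit$phi_hat, fit$sigma2_a, fit$sigma2_b,
                                   fit$loglik, as.numeric(fit$converged)),
                      se = NA_real_, statistic = NA_real_)
  utils::write.table(rbind(co, extra), path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Ingests (or simulates) the data, then per measure builds dyad tables
#' and association matrices, fits the full/reduced GLMM ladder, runs the
#' datastream permutation test for each model, computes per-sex-type
#' group contrasts, and draws sociograms. All artifacts are written under
#' `config$out_dir` together with a manifest recording the configuration,
#' seeds, package version and warnings. Any stage's hard error aborts
#' with the stage name.
#'
#' @param config a [run_config()].
#' @return (invisibly) list of in-memory results: `roster`, `records`,
#'   `dyad_table` and per-measure model/permutation results; the manifest
#'   is at `file.path(config$out_dir, "manifest.json")`.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character()
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }

  if (!is.null(config$generator)) {
    sim <- simulate_study(config$generator)
    ros <- sim$roster
    rec <- sim$records
  } else {
    ros <- load_roster(config$input$roster, min_age = config$min_age)
    rec <- load_focal_records(config$input$records, ros)
  }
  write_roster(ros, file.path(out, "roster.csv"))
  write_focal_records(rec, file.path(out, "focal_records.csv"))
  warnings_log <- c(warnings_log, run_log(ros), run_log(rec))

  dt <- build_dyad_table(rec, ros, identified_rule = config$identified_rule)
  utils::write.table(dt, file.path(out, "dyad_table.csv"), sep = ",",
                     row.names = FALSE, quote = FALSE)
  groups <- unique(ros$group_id[!ros$excluded])

  results <- list()
  seed_counter <- 0L
  for (measure in config$measures) {
    mdir <- file.path(out, measure)
    dir.create(mdir, showWarnings = FALSE)
    for (g in groups) {
      rg <- active_roster(ros, g)
      m <- build_association_matrix(rec, rg, measure,
                                    identified_rule = config$identified_rule)
      write_association_matrix(m, file.path(mdir, sprintf("matrix_%s.csv", g)))
      gr <- build_social_graph(m, rg)
      if (igraph::ecount(gr) > 0) {
        lay <- layout_sociogram(gr, seed = config$seed)
        com <- spinglass_communities(gr, seed = config$seed)
        igraph::V(gr)$community <- unname(com$membership[igraph::V(gr)$name])
        igraph::V(gr)$x <- lay[, 1]
        igraph::V(gr)$y <- lay[, 2]
        grDevices::pdf(file.path(mdir, sprintf("sociogram_%s.pdf", g)),
                       width = 7, height = 7)
        plot_sociogram(gr, layout = lay, communities = com,
                       main = sprintf("%s — %s", measure, g))
        grDevices::dev.off()
      } else {
        note("measure %s group %s: no edges, sociogram skipped", measure, g)
      }
      export_graph(gr, file.path(mdir, sprintf("sociogram_%s.graphml", g)))
    }

    for (part in measure_parts(measure)) {
      seed_counter <- seed_counter + 1L
      part_seed <- config$seed + 1000L * seed_counter
      if (part == "sri") {
        tab <- dt
        tab$y <- dt[[sri_column(measure)]]
        family <- "beta"
      } else {
        hs <- hurdle_split(dt, measure)
        if (part == "occurrence") {
          tab <- hs$occurrence; tab$y <- tab$occurrence; family <- "binomial"
        } else {
          tab <- hs$magnitude
          if (nrow(tab) < 10) {
            note("measure %s: too few nonzero dyads (%d), magnitude skipped",
                 measure, nrow(tab))
            next
          }
          tab$y <- tab$magnitude; family <- "beta"
        }
      }
      spec_full <- model_spec("y", family = family,
                              shared_variance = config$shared_variance)
      spec_red <- model_spec("y", family = family,
                             fixed = ~ sex_type + group_id + kin + age_diff,
                             shared_variance = config$shared_variance)
      fit_full <- fit_dyad_glmm(tab, spec_full, seed = part_seed)
      fit_red <- fit_dyad_glmm(tab, spec_red, seed = part_seed)
      write_fit(fit_full, file.path(mdir, sprintf("%s_fit_full.csv", part)))
      write_fit(fit_red, file.path(mdir, sprintf("%s_fit_reduced.csv", part)))
      lrt <- likelihood_ratio(fit_full, fit_red)
      jsonlite::write_json(unclass(lrt),
                           file.path(mdir, sprintf("%s_lrt.json", part)),
                           auto_unbox = TRUE, digits = NA)
      ctr <- group_contrasts(fit_full)
      utils::write.table(ctr, file.path(mdir, sprintf("%s_contrasts.csv", part)),
                         sep = ",", row.names = FALSE, quote = FALSE)
      perm <- NULL
      if (config$n_perm > 0) {
        perm <- run_permutation_test(
          rec, ros, measure = measure,
          response_type = if (part == "sri") "sri" else part,
          n_perm = config$n_perm, seed = part_seed,
          scheme = config$scheme,
          identified_rule = config$identified_rule,
          shared_variance = config$shared_variance)
        utils::write.table(
          data.frame(null_delta = perm$null_deltas),
          file.path(mdir, sprintf("%s_null_deltas.csv", part)),
          sep = ",", row.names = FALSE, quote = FALSE)
        pr <- perm[c("measure", "response_type", "scheme", "n_perm",
                     "observed_delta", "p_rand", "n_failed", "seed")]
        pr$p_rand_display <- format_p_rand(perm)
        jsonlite::write_json(pr,
                             file.path(mdir, sprintf("%s_perm.json", part)),
                             auto_unbox = TRUE, digits = NA)
        if (perm$n_failed > 0) {
          note("measure %s part %s: %d permuted fits failed",
               measure, part, perm$n_failed)
        }
      } else {
        note("measure %s part %s: permutations skipped (n_perm = 0)",
             measure, part)
      }
      results[[measure]][[part]] <- list(fit_full = fit_full,
                                         fit_reduced = fit_red,
                                         lrt = lrt, contrasts = ctr,
                                         perm = perm, seed = part_seed)
    }
  }

  cfg_path <- file.path(out, "config.yaml")
  write_run_config(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dyadnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_file = "config.yaml",
    config_md5 = unname(tools::md5sum(cfg_path)),
    measures = config$measures,
    n_perm = config$n_perm,
    groups = groups,
    n_individuals = nrow(ros),
    n_records = nrow(rec),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- summarize_results(out)
  writeLines(report, file.path(out, "report.txt"))
  invisible(list(roster = ros, records = rec, dyad_table = dt,
                 results = results, out_dir = out))
}

#' Summarize a completed run directory
#'
#' One block per measure mirroring the standard reporting shape: LRT
#' chi-square and df, the permutation p value, covariate estimates with
#' standard errors, and the per-sex-type group contrasts. Incomplete runs
#' yield a partial report with explicit gaps.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return character vector of report lines.
#' @export
summarize_results <- function(run_dir) {
  man_path <- file.path(run_dir, "manifest.json")
  if (!file.exists(man_path)) {
    stop_dyadnet("report", "no manifest.json in %s", run_dir)
  }
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  lines <- c(sprintf("dyadnet run summary (%s)", run_dir),
             sprintf("seed %d | %d individuals | %d focal records | n_perm %d",
                     man$seed, man$n_individuals, man$n_records, man$n_perm),
             "")
  for (measure in man$measures) {
    mdir <- file.path(run_dir, measure)
    lines <- c(lines, sprintf("== %s ==", measure))
    for (part in measure_parts(measure)) {
      lrt_p <- file.path(mdir, sprintf("%s_lrt.json", part))
      if (!file.exists(lrt_p)) {
        lines <- c(lines, sprintf("  [%s] missing", part))
        next
      }
      lrt <- jsonlite::read_json(lrt_p, simplifyVector = TRUE)
      perm_p <- file.path(mdir, sprintf("%s_perm.json", part))
      prand <- if (file.exists(perm_p)) {
        pj <- jsonlite::read_json(perm_p, simplifyVector = TRUE)
        sprintf("P_rand = %s (%d failed)", pj$p_rand_display, pj$n_failed)
      } else "P_rand: not run"
      lines <- c(lines, sprintf(
        "  [%s] sex_type x group: chi2 = %.2f, df = %d, p_analytic = %.4g; %s",
        part, lrt$chi2, lrt$df, lrt$p_analytic, prand))
      fit <- utils::read.table(file.path(mdir, sprintf("%s_fit_full.csv", part)),
                               header = TRUE, sep = ",",
                               stringsAsFactors = FALSE)
      for (cov in c("kin", "age_diff")) {
        row <- fit[fit$term == cov, ]
        if (nrow(row)) {
          lines <- c(lines, sprintf("      %s: estimate %.3f +/- %.3f",
                                    cov, row$estimate, row$se))
        }
      }
      ctr_p <- file.path(mdir, sprintf("%s_contrasts.csv", part))
      if (file.exists(ctr_p)) {
        ctr <- utils::read.table(ctr_p, header = TRUE, sep = ",",
                                 stringsAsFactors = FALSE)
        for (i in seq_len(nrow(ctr))) {
          lines <- c(lines, sprintf(
            "      %s group contrast: %.3f +/- %.3f (t = %.2f, p = %.3g)",
            ctr$sex_type[i], ctr$estimate[i], ctr$se[i], ctr$statistic[i],
            ctr$p[i]))
        }
      }
    }
    lines <- c(lines, "")
  }
  if (length(man$warnings)) {
    lines <- c(lines, "warnings:", paste(" -", man$warnings))
  }
  lines
}
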