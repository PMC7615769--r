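# End-to-end pipeline: simulate (optional) -> fit -> summarise ->
# classify -> report.  Configs are plain R lists or JSON files; outputs
# are deterministic (no timestamps) so re-running a config reproduces the
# report byte-identically.

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$out_dir)) stop_dbm("config needs out_dir")
  config$threshold <- config$threshold %||% 0.80
  config$min_pp <- config$min_pp %||% 2.0
  mc <- config$mcmc %||% list()
  config$mcmc <- list(
    iterations = mc$iterations %||% 2000,
    burn_fraction = mc$burn_fraction %||% 0.5,
    thin = mc$thin %||% 5,
    chains = mc$chains %||% 4,
    seed = mc$seed %||% (config$seed %||% 1)
  )
  config
}

#' Read back a tidy draws CSV
#'
#' Inverse of [write_draws_csv()].
#'
#' @param path CSV path
#' @param age_grid age grid used to restore `age_hi`
#' @return a [posterior_draws()]
#' @export
read_draws_csv <- function(path, age_grid = adult_age_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- do.call(paste, c(df[c("country", "year", "sex", "age_lo",
                               "category")], sep = "\r"))
  cells <- df[!duplicated(key), c("country", "year", "sex", "age_lo",
                                  "category")]
  cells$age_hi <- age_grid$age_hi[match(cells$age_lo, age_grid$age_lo)]
  D <- max(df$draw)
  draws <- matrix(df$prevalence, nrow = D)
  posterior_draws(draws, cells[c("country", "year", "sex", "age_lo",
                                 "age_hi", "category")], check = FALSE)
}

#' Run the full pipeline
#'
#' Stages: optional fixture simulation, model fitting for every category
#' and sex, draw-level summarisation (age-standardised category, combined,
#' and share estimates), country classification (direction of change of
#' the combined prevalence between the first and last year, dominance in
#' the last year, relevance), and a machine-readable report with counts
#' mirroring the reporting conventions.  Outputs: `estimates.csv`,
#' `probabilities.csv`, `classification.csv`, `report.json`,
#' `report.md`.
#'
#' @param config list or JSON path with fields: either `scenario` (+
#'   `seed`) to simulate inputs, or `inputs` naming
#'   `studies`/`hierarchy`/`age_standard` CSV paths (plus `years`);
#'   `out_dir`; optional `mcmc` settings (`iterations`, `burn_fraction`,
#'   `thin`, `chains`, `seed`), `threshold`, `min_pp`, `write_draws`
#' @return invisibly, the report list (also written as JSON); the
#'   `diagnostics_clean` entry reflects R-hat/ESS checks on monitored
#'   scalars
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  # -- inputs -------------------------------------------------------------
  if (!is.null(config$scenario)) {
    fx <- make_fixture(config$scenario, config$seed %||% 1,
                       file.path(config$out_dir, "inputs"))
    studies <- fx$studies
    hierarchy <- config_hierarchy(fx$configs$surface)
    standard <- read_age_standard(fx$paths$age_standard)
    years <- fx$configs$surface$years
    age_grid <- fx$configs$surface$age_grid
  } else {
    if (is.null(config$inputs)) stop_dbm("config needs scenario or inputs")
    studies <- read_study_table(config$inputs$studies,
                                window = unlist(config$years))
    hierarchy <- read_hierarchy(config$inputs$hierarchy)
    standard <- read_age_standard(config$inputs$age_standard)
    years <- seq(config$years[[1]], config$years[[2]])
    age_grid <- adult_age_grid()
  }
  bad <- validate_studies(studies)
  if (nrow(bad) > 0) {
    stop_dbm("stage 'validate' failed: %d invalid study rows (first: row %d, %s)",
             nrow(bad), bad$row[1], bad$rule[1])
  }

  # -- fit ----------------------------------------------------------------
  spec <- model_spec(
    years = years, age_grid = age_grid,
    iterations = config$mcmc$iterations,
    burn_fraction = config$mcmc$burn_fraction,
    thin = config$mcmc$thin, chains = config$mcmc$chains,
    seed = config$mcmc$seed)
  fit <- fit_model(studies, hierarchy, spec)

  # -- diagnostics --------------------------------------------------------
  diag_rows <- list()
  for (nm in names(fit$fits)) {
    f <- fit$fits[[nm]]
    d <- convergence_diagnostics(monitor_chains(f))
    d$param <- paste(nm, d$param, sep = ".")
    diag_rows[[nm]] <- d
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL

  # -- summarise ----------------------------------------------------------
  surf <- posterior_surface(fit)
  as_cat <- age_standardise(surf, standard)
  low <- subset_draws(as_cat, category = "low")
  obese <- subset_draws(as_cat, category = "obese")
  comb <- suppressWarnings(combined_prevalence(low, obese))
  # category-sum violations are reported, never altered
  n_sum_violations <- sum(comb$draws > 1 + 1e-12)
  share <- obesity_share(low, obese)
  estimates <- rbind(summarise_draws(low), summarise_draws(obese),
                     summarise_draws(comb), summarise_draws(share))
  estimates <- estimates[order(estimates$category, estimates$country,
                               estimates$sex, estimates$year), ]
  rownames(estimates) <- NULL

  y0 <- min(years); y1 <- max(years)
  probs <- posterior_prob_increase(subset_draws(comb, year = y1),
                                   subset_draws(comb, year = y0))
  dom <- posterior_prob_dominance(subset_draws(obese, year = y1),
                                  subset_draws(low, year = y1))
  d_end <- summarise_draws(subset_draws(comb, year = y1))
  d_start <- summarise_draws(subset_draws(comb, year = y0))
  key <- paste(probs$country, probs$sex)
  delta_pp <- 100 * (d_end$mean[match(key, paste(d_end$country,
                                                 d_end$sex))] -
                       d_start$mean[match(key, paste(d_start$country,
                                                     d_start$sex))])
  probabilities <- data.frame(
    country = probs$country, sex = probs$sex,
    p_increase = probs$p_increase, p_decrease = probs$p_decrease,
    p_obese_gt = dom$p_obese_gt[match(key, paste(dom$country, dom$sex))],
    p_low_gt = dom$p_low_gt[match(key, paste(dom$country, dom$sex))],
    delta_pp = delta_pp)

  # -- classify -----------------------------------------------------------
  classification <- data.frame(
    country = probabilities$country, sex = probabilities$sex,
    direction = classify_direction(probabilities$p_increase,
                                   probabilities$p_decrease,
                                   config$threshold),
    dominance = classify_dominance(probabilities$p_obese_gt,
                                   probabilities$p_low_gt,
                                   config$threshold),
    relevant_change = classify_relevant_change(
      probabilities$delta_pp,
      pmax(probabilities$p_increase, probabilities$p_decrease),
      config$threshold, config$min_pp))

  # -- report -------------------------------------------------------------
  counts <- list()
  for (sx in sort(unique(classification$sex))) {
    cl <- classification[classification$sex == sx, ]
    total <- nrow(cl)
    counts[[sx]] <- list(
      total = total,
      increase = count_countries(cl$direction == "increase", total),
      decrease = count_countries(cl$direction == "decrease", total),
      obesity_dominant = count_countries(cl$dominance == "obesity-dominant",
                                         total),
      low_dominant = count_countries(cl$dominance == "low-dominant", total),
      indistinguishable = count_countries(
        cl$dominance == "indistinguishable", total),
      relevant_change = count_countries(cl$relevant_change, total))
  }
  report <- list(
    scenario = config$scenario %||% "files",
    seed = config$seed %||% config$mcmc$seed,
    years = c(y0, y1),
    threshold = config$threshold, min_pp = config$min_pp,
    counts = counts,
    n_category_sum_violations = n_sum_violations,
    diagnostics = list(
      max_rhat = max(diagnostics$rhat, na.rm = TRUE),
      min_ess = min(diagnostics$ess, na.rm = TRUE),
      clean = !any(diagnostics$flagged)))

  utils::write.csv(estimates, file.path(config$out_dir, "estimates.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(probabilities,
                   file.path(config$out_dir, "probabilities.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(classification,
                   file.path(config$out_dir, "classification.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(diagnostics,
                   file.path(config$out_dir, "diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_markdown(report),
             file.path(config$out_dir, "report.md"))
  if (isTRUE(config$write_draws)) {
    write_draws_csv(as_cat, file.path(config$out_dir, "draws.csv"))
  }
  invisible(report)
}

report_markdown <- function(report) {
  lines <- c(
    "# Double-burden trend report",
    "",
    sprintf("Scenario: %s; years %d-%d; threshold %.2f.",
            report$scenario, report$years[1], report$years[2],
            report$threshold),
    "")
  for (sx in names(report$counts)) {
    cn <- report$counts[[sx]]
    lines <- c(lines, sprintf(
      paste0("For %s, combined prevalence increased in %d countries ",
             "(%d%%) and decreased in %d (%d%%) of %d countries; ",
             "obesity was dominant in %d (%d%%), the low category in ",
             "%d (%d%%), and the two were indistinguishable in %d (%d%%)."),
      sx, cn$increase$count, cn$increase$percent, cn$decrease$count,
      cn$decrease$percent, cn$total, cn$obesity_dominant$count,
      cn$obesity_dominant$percent, cn$low_dominant$count,
      cn$low_dominant$percent, cn$indistinguishable$count,
      cn$indistinguishable$percent))
  }
  c(lines, "",
    sprintf("Diagnostics: max R-hat %.3f, min ESS %.0f, %s.",
            report$diagnostics$max_rhat, report$diagnostics$min_ess,
            if (report$diagnostics$clean) "clean" else "flagged"))
}
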