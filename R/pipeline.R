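# End-to-end orchestration: simulate -> measure -> compare, with optional
# blinding, a provenance manifest, and summary plots.

#' Configuration for an end-to-end pipeline run
#'
#' @param out_dir output directory (created if missing).
#' @param preset cohort preset name (see [cohort_preset()]), used when no
#'   `input_csv` is given.
#' @param input_csv optional path to an existing long-format cohort CSV
#'   (columns as written by [gen_cohort()]); must exist if supplied.
#' @param n_animals_per_condition animals per condition for simulation.
#' @param seed integer seed recorded in every output.
#' @param blinded mask condition labels during the measurement/summary
#'   stages; the code-to-label key is applied only at the statistics stage.
#'   Mirrors double-blinded scoring: upstream numbers cannot depend on
#'   labels, and blinded and unblinded runs agree numerically.
#' @param alpha significance level for the Tukey stage.
#' @param make_plots write per-endpoint mean ± SEM PNG plots.
#' @return An object of class `wt_run_config`.
#' @export
run_config <- function(out_dir, preset = "contractility", input_csv = NULL,
                       n_animals_per_condition = 30L, seed = 1L,
                       blinded = TRUE, alpha = 0.05, make_plots = TRUE) {
  if (!is.null(input_csv) && !file.exists(input_csv))
    stop("config refers to a missing input file: ", input_csv, call. = FALSE)
  structure(list(out_dir = out_dir, preset = preset, input_csv = input_csv,
                 n_animals_per_condition = as.integer(n_animals_per_condition),
                 seed = seed, blinded = isTRUE(blinded), alpha = alpha,
                 make_plots = isTRUE(make_plots)),
            class = "wt_run_config")
}

#' Run the simulate -> measure -> compare pipeline
#'
#' Stages: (1) obtain a per-animal cohort table, either simulated from the
#' configured preset or read from `input_csv`; (2) summarize each endpoint
#' per condition (under opaque condition codes when blinded); (3) unblind
#' and run one-way ANOVA + Tukey HSD per endpoint; (4) write per-stage
#' CSVs, optional plots, and a `manifest.json` listing every output file
#' with its MD5 content hash, the seed and all parameters. Outputs contain
#' no timestamps: rerunning with the same config and seed reproduces them
#' byte for byte.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list of class `wt_run`: `cohort`, `summaries`,
#'   `anova`, `tukey` (per endpoint), `files`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "wt_run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character()
  log_msg <- function(stage, ...)
    message(sprintf("[wormtwitch:%s] %s", stage, sprintf(...)))

  # stage 1: simulate (or load)
  if (is.null(config$input_csv)) {
    log_msg("simulate", "preset '%s', %d animals/condition, seed %s",
            config$preset, config$n_animals_per_condition, format(config$seed))
    gen <- gen_cohort(cohort_preset(config$preset,
                                    config$n_animals_per_condition, config$seed))
    cohort <- gen$table
  } else {
    if (!file.exists(config$input_csv))
      stop("simulate stage: missing input file: ", config$input_csv, call. = FALSE)
    log_msg("simulate", "loading cohort from %s", config$input_csv)
    cohort <- read.csv(config$input_csv)
  }

  conds <- sort(unique(cohort$condition))
  key <- data.frame(condition = conds,
                    code = sprintf("group_%02d", seq_along(conds)))
  masked <- cohort
  masked$condition <- key$code[match(cohort$condition, key$condition)]
  masked$genotype <- NULL  # genotype would unblind the condition
  measured <- if (config$blinded) masked else cohort
  write.csv(measured[order(measured$endpoint, measured$condition, measured$animal_id), ],
            out("cohort_measurements.csv"), row.names = FALSE)
  files <- c(files, "cohort_measurements.csv")
  if (config$blinded) {
    write.csv(key, out("blinding_key.csv"), row.names = FALSE)
    files <- c(files, "blinding_key.csv")
  }

  # stage 2: per-endpoint summaries (on blinded codes when masked)
  endpoints <- sort(unique(cohort$endpoint))
  summaries <- lapply(endpoints, function(ep) {
    s <- suppressWarnings(
      summarize_groups(value ~ condition, measured[measured$endpoint == ep, ]))
    s$endpoint <- ep
    s
  })
  summary_tab <- do.call(rbind, summaries)
  write.csv(summary_tab, out("group_summary.csv"), row.names = FALSE)
  files <- c(files, "group_summary.csv")
  log_msg("measure", "%d endpoint(s), %d condition(s)", length(endpoints), length(conds))

  # stage 3: unblind and compare
  anova_rows <- list(); tukey_rows <- list()
  fits <- list(); hsds <- list()
  for (ep in endpoints) {
    d <- cohort[cohort$endpoint == ep, ]
    fit <- tryCatch(suppressWarnings(one_way_anova(value ~ condition, d)),
                    error = function(e)
                      stop("stats stage failed for endpoint '", ep, "': ",
                           conditionMessage(e), call. = FALSE))
    hsd <- tukey_hsd(fit, alpha = config$alpha)
    fits[[ep]] <- fit; hsds[[ep]] <- hsd
    anova_rows[[ep]] <- data.frame(endpoint = ep, F = fit$F,
                                   df_between = fit$df_between,
                                   df_within = fit$df_within,
                                   p_value = fit$p_value)
    tr <- as.data.frame(hsd)
    tr <- cbind(endpoint = ep, tr)
    tukey_rows[[ep]] <- tr
  }
  write.csv(do.call(rbind, anova_rows), out("anova_results.csv"), row.names = FALSE)
  write.csv(do.call(rbind, tukey_rows), out("tukey_results.csv"), row.names = FALSE)
  files <- c(files, "anova_results.csv", "tukey_results.csv")
  log_msg("stats", "ANOVA + Tukey written for %d endpoint(s)", length(endpoints))

  # stage 4: plots (best effort; requires a PNG device)
  if (config$make_plots) {
    for (ep in endpoints) {
      fname <- sprintf("summary_%s.png", gsub("[^A-Za-z0-9]+", "_", ep))
      ok <- tryCatch({
        grDevices::png(out(fname), width = 640, height = 480)
        plot_group_summary(fits[[ep]]$groups, ep)
        grDevices::dev.off()
        TRUE
      }, error = function(e) {
        try(grDevices::dev.off(), silent = TRUE)
        warning("plot stage skipped for '", ep, "': ", conditionMessage(e),
                call. = FALSE)
        FALSE
      })
      if (ok) files <- c(files, fname)
    }
  }

  manifest <- list(
    package = "wormtwitch",
    seed = config$seed,
    preset = if (is.null(config$input_csv)) config$preset else NULL,
    input_csv = config$input_csv,
    n_animals_per_condition = config$n_animals_per_condition,
    blinded = config$blinded,
    alpha = config$alpha,
    files = lapply(files, function(f)
      list(name = f, md5 = unname(tools::md5sum(out(f))))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  files <- c(files, "manifest.json")
  log_msg("manifest", "%d file(s) hashed", length(manifest$files))

  invisible(structure(list(cohort = cohort, summaries = summary_tab,
                           anova = fits, tukey = hsds,
                           files = file.path(config$out_dir, files),
                           manifest = manifest),
                      class = "wt_run"))
}

# Mean ± SEM bar plot for one endpoint.
plot_group_summary <- function(groups, endpoint) {
  op <- par(mar = c(9, 4, 2, 1)); on.exit(par(op))
  mid <- barplot(groups$mean, names.arg = groups$condition, las = 2,
                 ylab = endpoint, col = "grey80",
                 ylim = c(0, max(groups$mean + groups$sem) * 1.15))
  arrows(mid, groups$mean - groups$sem, mid, groups$mean + groups$sem,
         angle = 90, code = 3, length = 0.05)
  invisible(mid)
}
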