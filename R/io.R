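# Round half-up for display columns (R's round() is round-half-even).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Write a frequency/coefficient table (attribute percentages + SI/DSI)
#'
#' One row per need with attribute percentages, SI and DSI, plus an average
#' row carrying the coefficient means. With `digits` set, percentages are
#' rendered to 2 decimal places (percent) and coefficients to `digits`;
#' with `digits = NULL` full precision is written.
#'
#' @param analysis A [kano_analysis()] result.
#' @param path Output CSV path.
#' @param digits Coefficient display digits (default 3), or `NULL` for full
#'   precision.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(analysis, path, digits = 3) {
  freq <- analysis$frequencies
  att <- kano_attributes()
  pct <- as.data.frame(freq[, att, drop = FALSE] / freq$n * 100)
  co <- analysis$coefficients
  out <- data.frame(need_id = freq$need_id, pct,
                    SI = co$si, DSI = co$dsi,
                    stringsAsFactors = FALSE)
  avg <- data.frame(need_id = "Average", t(rep(NA_real_, length(att))),
                    SI = mean(co$si), DSI = mean(co$dsi))
  names(avg) <- names(out)
  out <- rbind(out, avg)
  if (!is.null(digits)) {
    out[att] <- lapply(out[att], round_half_up, digits = 2)
    out$SI <- round_half_up(out$SI, digits)
    out$DSI <- round_half_up(out$DSI, digits)
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Write the importance/priority table
#'
#' One row per need: quadrant attribute, satisfaction sensitivity, the global
#' sensitivity rank and the within-attribute priority rank, ordered by the
#' overall priority (attribute hierarchy M > O > A > I, then within-attribute
#' rank).
#'
#' @inheritParams write_frequency_table
#' @return `path`, invisibly.
#' @export
write_importance_table <- function(analysis, path, digits = 3) {
  out <- analysis$ranking
  if (!is.null(digits)) out$s <- round_half_up(out$s, digits)
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a subgroup comparison table
#'
#' @param comparison A [compare_subgroups()] result.
#' @param path Output CSV path.
#' @param digits Display digits for coefficients (default 3), `NULL` for
#'   full precision.
#' @return `path`, invisibly.
#' @export
write_subgroup_table <- function(comparison, path, digits = 3) {
  out <- comparison
  if (!is.null(digits)) {
    out$si <- round_half_up(out$si, digits)
    out$dsi <- round_half_up(out$dsi, digits)
    out$chi2 <- round_half_up(out$chi2, digits)
    out$p <- round_half_up(out$p, digits)
  }
  write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input Path to a wide responses CSV, or a wide data.frame.
#' @param output_dir Directory for the report bundle.
#' @param screening A [screening_config()].
#' @param subgroup_fields Demographic fields to compare (default: region,
#'   field_of_work, job_position).
#' @param scheme Chi-square category scheme (see [chi_square_attributes()]).
#' @param digits Display rounding for report tables.
#' @param seed Seed recorded in the run log (the analysis itself is
#'   deterministic).
#' @param catalog Need catalog.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir,
                            screening = screening_config(),
                            subgroup_fields = c("region", "field_of_work",
                                                "job_position"),
                            scheme = "full",
                            digits = 3,
                            seed = 1L,
                            catalog = ccec_need_catalog()) {
  stopifnot(scheme %in% c("full", "drop_rq", "target_vs_rest"))
  bad <- setdiff(subgroup_fields, demographic_fields())
  if (length(bad) > 0) {
    stop("unknown subgroup field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(input = input, output_dir = output_dir,
                 screening = screening, subgroup_fields = subgroup_fields,
                 scheme = scheme, digits = digits, seed = as.integer(seed),
                 catalog = catalog),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields of [pipeline_config()] plus the `screening` sub-map
#' (`exclude_missing`, `exclude_straight_line`, `q_max`). Round-trips
#' unchanged through [yaml::write_yaml()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  scr <- do.call(screening_config, if (is.null(y$screening)) list() else y$screening)
  args <- y[setdiff(names(y), "screening")]
  args$screening <- scr
  do.call(pipeline_config, args)
}

#' Run the full needs-assessment pipeline
#'
#' Reads (or accepts) the wide respondent table, screens questionnaires,
#' tabulates attributes, computes coefficients, centroid, quadrant
#' classification and rankings, compares the configured demographic
#' subgroups, and writes the report bundle: frequency and importance tables
#' (display-rounded and full-precision variants), subgroup tables, the
#' quadrant scatter plot, and a run log.
#'
#' @param config A [pipeline_config()].
#' @return A `kano_report` list (screening, analysis, subgroups, file
#'   paths), invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  catalog <- config$catalog
  records <- if (is.data.frame(config$input)) {
    validate_responses(config$input, catalog)
  } else {
    read_responses(config$input, catalog)
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  screening <- screen_respondents(records, catalog, config$screening)
  if (screening$n_valid == 0L) stop("no valid questionnaires after screening",
                                    call. = FALSE)
  freq <- tabulate_needs(screening$valid, catalog)
  analysis <- kano_analysis(freq)

  paths <- list(
    frequency = file.path(config$output_dir, "attribute_frequencies.csv"),
    frequency_full = file.path(config$output_dir, "attribute_frequencies_full.csv"),
    importance = file.path(config$output_dir, "importance_ranking.csv"),
    importance_full = file.path(config$output_dir, "importance_ranking_full.csv"),
    plot = file.path(config$output_dir, "quadrant_plot.png"),
    log = file.path(config$output_dir, "run_log.txt")
  )
  write_frequency_table(analysis, paths$frequency, digits = config$digits)
  write_frequency_table(analysis, paths$frequency_full, digits = NULL)
  write_importance_table(analysis, paths$importance, digits = config$digits)
  write_importance_table(analysis, paths$importance_full, digits = NULL)

  subgroups <- list()
  for (f in config$subgroup_fields) {
    if (!f %in% names(screening$valid)) next
    n_groups <- length(unique(screening$valid[[f]]))
    if (n_groups != 2L) {
      warning("skipping subgroup field '", f, "': ", n_groups,
              " observed categories (need 2)", call. = FALSE)
      next
    }
    cmp <- tryCatch(
      compare_subgroups(screening$valid, f, catalog, scheme = config$scheme),
      error = function(e) {
        warning("subgroup comparison failed for '", f, "': ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(cmp)) next
    subgroups[[f]] <- cmp
    p <- file.path(config$output_dir, paste0("subgroup_", f, ".csv"))
    write_subgroup_table(cmp, p, digits = config$digits)
    paths[[paste0("subgroup_", f)]] <- p
  }

  plt <- plot_quadrants(analysis)
  ggplot2::ggsave(paths$plot, plt, width = 7, height = 6, dpi = 150)

  excl <- table(screening$excluded$reason)
  log_lines <- c(
    sprintf("questionnaires collected: %d", screening$n_input),
    sprintf("questionnaires valid: %d", screening$n_valid),
    sprintf("effective rate: %.2f%%", 100 * screening$effective_rate),
    sprintf("excluded by %s: %d", names(excl), as.integer(excl)),
    sprintf("centroid: mean SI = %.6f, mean |DSI| = %.6f",
            analysis$centroid$mean_si, analysis$centroid$mean_abs_dsi),
    sprintf("need %s: attribute %s, S = %.6f, sensitivity rank %d, within-attribute rank %d",
            analysis$ranking$need_id, analysis$ranking$attribute,
            analysis$ranking$s, analysis$ranking$sensitivity_rank,
            analysis$ranking$within_attribute_rank),
    sprintf("seed: %d", config$seed)
  )
  writeLines(log_lines, paths$log)

  invisible(structure(list(screening = screening, analysis = analysis,
                           subgroups = subgroups, paths = paths,
                           config = config),
                      class = "kano_report"))
}
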