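# End-to-end orchestration: per-subject pipeline, cohort aggregation,
# reporting artifacts.

#' Analysis run configuration
#'
#' Collects the analysis constants.  Defaults are the conventional
#' resting short-term HRV settings this pipeline is built around: 500 Hz
#' channels, a 5 s sliding window on a 0.1 s grid, 250-1500 ms R-R
#' gating, the 0.15-0.40 Hz HF band, alpha 0.05.  Every override of a
#' default is recorded and echoed by [config_echo()].
#'
#' @param fs sampling rate, Hz.
#' @param guard_s edge guard excluded from correlations, seconds.
#' @param window_s sliding window, seconds.
#' @param grid_s HRV grid spacing, seconds.
#' @param rr_bounds_ms inclusive R-R validity range, ms.
#' @param hf_band_hz HF band, Hz.
#' @param alpha significance level.
#' @param min_pairs minimum grid points per correlation cell.
#' @param hf_input HF estimator input, `"beats"` or `"resampled"`.
#' @param thin correlation grid thinning factor (1 = all points).
#' @param use_true_beats consume simulated ground-truth beat times
#'   instead of running the detector (simulation studies only).
#' @param seed run seed (recorded in artifacts).
#' @return object of class `run_config`.
#' @export
run_config <- function(fs = 500, guard_s = 10, window_s = 5, grid_s = 0.1,
                       rr_bounds_ms = c(250, 1500),
                       hf_band_hz = c(0.15, 0.40), alpha = 0.05,
                       min_pairs = 100, hf_input = "beats", thin = 1,
                       use_true_beats = FALSE, seed = 1) {
  overridden <- names(as.list(match.call())[-1])
  cfg <- list(fs = fs, guard_s = guard_s, window_s = window_s,
              grid_s = grid_s, rr_bounds_ms = rr_bounds_ms,
              hf_band_hz = hf_band_hz, alpha = alpha,
              min_pairs = min_pairs, hf_input = hf_input, thin = thin,
              use_true_beats = use_true_beats, seed = as.integer(seed),
              overridden = overridden)
  stopifnot(fs > 0, guard_s >= 0, window_s > 0, grid_s > 0,
            length(rr_bounds_ms) == 2, rr_bounds_ms[1] < rr_bounds_ms[2],
            length(hf_band_hz) == 2, hf_band_hz[1] < hf_band_hz[2],
              alpha > 0, alpha < 1)
  class(cfg) <- "run_config"
  cfg
}

#' Echo a run configuration with provenance per parameter
#'
#' @param config a [run_config()].
#' @return data frame `parameter`, `value`, `source` (`"default"` or
#'   `"override"`).
#' @export
config_echo <- function(config) {
  stopifnot(inherits(config, "run_config"))
  fields <- setdiff(names(config), "overridden")
  data.frame(parameter = fields,
             value = vapply(fields, function(f)
               paste(format(config[[f]]), collapse = ", "), character(1)),
             source = ifelse(fields %in% config$overridden,
                             "override", "default"),
             row.names = NULL)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(config_echo(x), right = FALSE)
  invisible(x)
}

#' Run the full pipeline for one subject
#'
#' Respiratory decomposition, R-peak detection (or ground-truth beats),
#' R-R gating and repair, the sliding HRV track, and the 3 x 3
#' correlation matrix.  Deterministic given inputs and config.
#'
#' @param resp respiration: a `sampled_signal` or a CSV path readable by
#'   [read_signal_csv()].
#' @param ecg ECG: a `sampled_signal` or CSV path; may be `NULL` when
#'   `beat_times` is supplied.
#' @param config a [run_config()].
#' @param subject_id label used in artifacts.
#' @param beat_times optional known beat times (seconds); used instead of
#'   detection when `config$use_true_beats` is `TRUE`.
#' @param out_dir optional directory: writes the decomposition, R-R and
#'   HRV CSVs plus the correlation table.
#' @return object of class `subject_result`: `id`, `correlations` (a
#'   `subject_correlations`), `decomp`, `rr`, `track`.
#' @export
run_subject <- function(resp, ecg, config = run_config(),
                        subject_id = "s01", beat_times = NULL,
                        out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.character(resp)) resp <- read_signal_csv(resp)
  if (is.character(ecg)) ecg <- read_signal_csv(ecg)
  if (!is.null(ecg) &&
      abs(signal_duration(resp) - signal_duration(ecg)) > 1)
    stop("respiration and ECG durations differ by more than 1 s")
  decomp <- decompose_respiration(resp, guard_s = config$guard_s)
  if (config$use_true_beats && !is.null(beat_times)) {
    bt <- beat_times
  } else {
    if (is.null(ecg)) stop("no ECG channel and no usable beat times")
    bt <- detect_r_peaks(ecg)
  }
  rr <- clean_and_interpolate_rr(bt, bounds_ms = config$rr_bounds_ms)
  track <- sliding_hrv(rr, window_s = config$window_s,
                       grid_s = config$grid_s,
                       hf_band = config$hf_band_hz,
                       hf_input = config$hf_input)
  corr <- subject_correlations(decomp, track,
                               min_pairs = config$min_pairs,
                               thin = config$thin)
  res <- structure(list(id = subject_id, correlations = corr,
                        decomp = decomp, rr = rr, track = track),
                   class = "subject_result")
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_decomposition_csv(decomp,
                            file.path(out_dir, paste0(subject_id, "_decomposition.csv")))
    write_rr_csv(rr, file.path(out_dir, paste0(subject_id, "_rr.csv")))
    write_hrv_csv(track, file.path(out_dir, paste0(subject_id, "_hrv.csv")))
    write_csv_full(correlation_table(list(res)),
                   file.path(out_dir, paste0(subject_id, "_correlations.csv")))
  }
  res
}

#' @export
print.subject_result <- function(x, ...) {
  cat(sprintf("<subject_result '%s'>\n", x$id))
  print(x$correlations)
  invisible(x)
}

# Write a data frame with numeric columns rendered at full double
# precision (%.17g), so recomputing statistics from the saved table is
# bit-identical to the in-memory run.
write_csv_full <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Long-format correlation table for a list of subject results
#'
#' @param results list of `subject_result`.
#' @return data frame `subject`, `measure`, `index`, `rho`, `z`,
#'   `n_pairs`.
#' @export
correlation_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    co <- r$correlations
    mm <- rownames(co$rho); ii <- colnames(co$rho)
    data.frame(subject = r$id,
               measure = rep(mm, times = length(ii)),
               index = rep(ii, each = length(mm)),
               rho = as.vector(co$rho), z = as.vector(co$z),
               n_pairs = as.vector(co$n_pairs))
  }))
}

#' Cohort statistics from a long correlation table
#'
#' The aggregation half of [run_cohort()], reusable from saved
#' per-subject tables: per parasympathetic index, the subjects x
#' measures Fisher-z matrix, its repeated-measures ANOVA and Bonferroni
#' pairwise comparisons.
#'
#' @param tab data frame as produced by [correlation_table()].
#' @param alpha significance level carried into the report.
#' @param excluded character vector of excluded-subject messages.
#' @return object of class `cohort_stats`.
#' @export
cohort_stats_from_table <- function(tab, alpha = 0.05,
                                    excluded = character(0)) {
  measures <- c("waveform", "amplitude", "rate")
  indices <- c("hf", "rmssd", "cvi")
  subjects <- unique(tab$subject)
  per_index <- list()
  for (ix in indices) {
    z <- sapply(measures, function(m) {
      v <- merge(data.frame(subject = subjects),
                 tab[tab$measure == m & tab$index == ix,
                     c("subject", "z")],
                 by = "subject", all.x = TRUE, sort = FALSE)
      v$z[match(subjects, v$subject)]
    })
    rownames(z) <- subjects
    per_index[[ix]] <- list(z = z, anova = rm_anova(z),
                            pairwise = bonferroni_pairwise(z))
  }
  structure(list(per_index = per_index, table = tab, alpha = alpha,
                 n_subjects = length(subjects), excluded = excluded),
            class = "cohort_stats")
}

#' Run the full pipeline over a cohort
#'
#' Applies [run_subject()] to each subject with crash isolation (a
#' failing subject is excluded with its reason logged, mirroring the
#' visual exclusion of unusable recordings), then aggregates: per
#' parasympathetic index a repeated-measures ANOVA over the Fisher-z
#' correlations of the three respiratory measures, with
#' Bonferroni-corrected pairwise comparisons.
#'
#' @param cohort a `cardioresp_cohort`, or a list whose elements have
#'   `resp`, `ecg` (or `truth$true_beat_times`) and optionally `id`.
#' @param config a [run_config()].
#' @param out_dir optional directory for artifacts: correlation table
#'   CSV, per-index ANOVA and pairwise CSVs, a JSON summary, a run log.
#' @param figures also write a summary figure (PNG) under `out_dir`.
#' @return a `cohort_stats` object.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(5, sim_config(duration_s = 90, fs = 50, seed = 11),
#'                        scenario = "depth-coupled", ecg = FALSE)
#' cs <- run_cohort(coh, run_config(fs = 50, use_true_beats = TRUE))
#' summary(cs)
#' }
#' @export
run_cohort <- function(cohort, config = run_config(), out_dir = NULL,
                       figures = FALSE) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  excluded <- character(0)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    id <- if (!is.null(s$id)) s$id else sprintf("s%02d", i)
    res <- tryCatch(
      run_subject(s$resp, s$ecg, config, subject_id = id,
                  beat_times = s$truth$true_beat_times),
      error = function(e) conditionMessage(e))
    if (inherits(res, "subject_result")) results[[length(results) + 1]] <- res
    else excluded <- c(excluded, paste0(id, ": ", res))
  }
  if (length(results) < 3)
    stop("fewer than 3 usable subjects; exclusions:\n  ",
         paste(excluded, collapse = "\n  "))
  tab <- correlation_table(results)
  cs <- cohort_stats_from_table(tab, alpha = config$alpha,
                                excluded = excluded)
  cs$config <- config
  if (!is.null(out_dir)) write_cohort_report(cs, out_dir, figures = figures)
  cs
}

#' Write cohort report artifacts
#'
#' @param cs a `cohort_stats`.
#' @param out_dir destination directory.
#' @param figures also write the summary figure.
#' @return `out_dir`, invisibly.
#' @export
write_cohort_report <- function(cs, out_dir, figures = FALSE) {
  stopifnot(inherits(cs, "cohort_stats"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_csv_full(cs$table, file.path(out_dir, "correlations.csv"))
  an <- do.call(rbind, lapply(names(cs$per_index), function(ix) {
    a <- cs$per_index[[ix]]$anova
    data.frame(index = ix, F = a$F, df1 = a$df[1], df2 = a$df[2],
               p = a$p, partial_eta_sq = a$partial_eta_sq, n = a$n)
  }))
  utils::write.csv(an, file.path(out_dir, "anova.csv"), row.names = FALSE)
  pw <- do.call(rbind, lapply(names(cs$per_index), function(ix)
    cbind(index = ix, cs$per_index[[ix]]$pairwise)))
  utils::write.csv(pw, file.path(out_dir, "pairwise.csv"),
                   row.names = FALSE)
  summ <- list(n_subjects = cs$n_subjects, alpha = cs$alpha,
               excluded = cs$excluded,
               anova = lapply(cs$per_index, function(pi)
                 list(F = pi$anova$F, df = pi$anova$df, p = pi$anova$p,
                      partial_eta_sq = pi$anova$partial_eta_sq,
                      means = as.list(pi$anova$means))),
               pairwise = lapply(cs$per_index, function(pi)
                 pi$pairwise))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(cs$config)) {
    ec <- config_echo(cs$config)
    writeLines(c("run configuration:",
                 sprintf("  %-14s = %-12s [%s]", ec$parameter, ec$value,
                         ec$source),
                 if (length(cs$excluded))
                   c("excluded subjects:", paste0("  ", cs$excluded))
                 else "excluded subjects: none"),
               file.path(out_dir, "run_log.txt"))
  }
  if (figures) {
    grDevices::png(file.path(out_dir, "cohort_summary.png"),
                   width = 1200, height = 500, res = 110)
    plot(cs)
    grDevices::dev.off()
  }
  invisible(out_dir)
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat(sprintf("<cohort_stats: %d subjects, %d excluded, alpha = %g>\n",
              x$n_subjects, length(x$excluded), x$alpha))
  for (ix in names(x$per_index)) {
    cat(sprintf("  %-6s", toupper(ix)))
    print(x$per_index[[ix]]$anova)
  }
  invisible(x)
}

#' @export
summary.cohort_stats <- function(object, ...) {
  print(object)
  for (ix in names(object$per_index)) {
    cat("\n", toupper(ix), "pairwise (Bonferroni):\n")
    pw <- object$per_index[[ix]]$pairwise
    pw[-1] <- lapply(pw[-1], function(v) signif(v, 4))
    print(pw, row.names = FALSE)
  }
  if (length(object$excluded)) {
    cat("\nexcluded subjects:\n")
    cat(paste0("  ", object$excluded, collapse = "\n"), "\n")
  }
  invisible(object)
}

#' Cohort summary figure
#'
#' Per parasympathetic index, the per-subject Fisher-z correlations of
#' the three respiratory measures (jittered points) with mean +/- SE
#' bars.
#'
#' @param x a `cohort_stats`.
#' @param ... ignored.
#' @export
plot.cohort_stats <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, length(x$per_index)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cols <- c(waveform = "darkgreen", amplitude = "red", rate = "blue")
  for (ix in names(x$per_index)) {
    z <- x$per_index[[ix]]$z
    k <- ncol(z)
    graphics::plot(NA, xlim = c(0.5, k + 0.5),
                   ylim = range(z, na.rm = TRUE) + c(-0.05, 0.05),
                   xaxt = "n", xlab = "", ylab = "Fisher z",
                   main = toupper(ix))
    graphics::axis(1, at = seq_len(k), labels = colnames(z))
    for (j in seq_len(k)) {
      v <- z[, j]
      graphics::points(jitter(rep(j, length(v)), amount = 0.08), v,
                       pch = 20, col = "grey60")
      m <- mean(v, na.rm = TRUE)
      se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
      graphics::segments(j - 0.15, m, j + 0.15, m, lwd = 2,
                         col = cols[colnames(z)[j]])
      graphics::arrows(j, m - se, j, m + se, angle = 90, code = 3,
                       length = 0.04)
    }
  }
  invisible(x)
}
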