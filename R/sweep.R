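# Orchestration of the sensor-length x architecture sweeps: sample channels
# once per sensor length, optimize each architecture with random restarts,
# evaluate the measure panel per restart, and summarize trends.

#' Sweep configuration
#'
#' Desk-scale defaults: sensor lengths 0.5 to 2.75 in steps of 0.25, all
#' three architectures, 2e5 samples per length, 20 restarts with at least
#' 200 EM iterations at tolerance 1e-5. `paper_scale = TRUE` restores the
#' published protocol (2e7 samples, 100 restarts, at least 1000
#' iterations).
#'
#' @param sensor_lengths Ascending positive sensor lengths.
#' @param architectures Character vector of [architecture()] names.
#' @param n_samples Rollout steps per sensor length.
#' @param n_restarts Random initial policies per grid cell.
#' @param min_iters Minimum EM iterations.
#' @param tol EM stopping tolerance on the likelihood change.
#' @param seed Integer base seed.
#' @param track A [make_track()] object.
#' @param paper_scale If `TRUE`, override `n_samples`, `n_restarts`,
#'   `min_iters` with the published values.
#' @param out_dir Optional directory for incremental per-cell persistence;
#'   completed cells are skipped on re-run.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(sensor_lengths = seq(0.5, 2.75, by = 0.25),
                         architectures = c("fully_coupled",
                                           "controller_driven", "reactive"),
                         n_samples = 2e5, n_restarts = 20L, min_iters = 200L,
                         tol = 1e-5, seed = 1L, track = default_track(),
                         paper_scale = FALSE, out_dir = NULL) {
  if (is.unsorted(sensor_lengths, strictly = TRUE) || any(sensor_lengths <= 0)) {
    stop("sensor_lengths must be positive and strictly ascending")
  }
  if (paper_scale) {
    n_samples <- 2e7; n_restarts <- 100L; min_iters <- 1000L
  }
  structure(list(sensor_lengths = sensor_lengths,
                 architectures = architectures, n_samples = n_samples,
                 n_restarts = n_restarts, min_iters = min_iters, tol = tol,
                 seed = as.integer(seed), track = track, out_dir = out_dir),
            class = "sweep_config")
}

.lf_cell_file <- function(out_dir, sl, arch) {
  file.path(out_dir, sprintf("cell_SL%03d_%s.csv", round(sl * 100), arch))
}

#' Run a sensor-length x architecture sweep
#'
#' For each sensor length the channels are sampled once; each architecture
#' is then optimized with `n_restarts` random initial policies and the seven
#' measures are evaluated on every optimized system. With
#' `config$out_dir` set, each completed grid cell is written to CSV and
#' skipped on re-run (the sweep is resumable by cell).
#'
#' @param config A [sweep_config()].
#' @param verbose Print per-cell progress.
#' @return A `loop_sweep` tibble: one row per sensor length, architecture
#'   and restart, with `p_g1`, `n_iters`, `converged`, the seven measure
#'   columns and `trace_min_delta` (the most negative likelihood step seen,
#'   for monotonicity auditing).
#' @export
run_sweep <- function(config = sweep_config(), verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  failures <- character(0)
  rows <- list()
  for (sl in config$sensor_lengths) {
    cfg <- sensor_config(length = sl)
    channels <- NULL
    for (arch in config$architectures) {
      cell_id <- sprintf("SL=%.2f/%s", sl, arch)
      if (!is.null(out_dir) && file.exists(.lf_cell_file(out_dir, sl, arch))) {
        rows[[cell_id]] <- utils::read.csv(.lf_cell_file(out_dir, sl, arch))
        next
      }
      res <- tryCatch({
        if (is.null(channels)) {
          channels <- sample_channels(config$track, cfg,
                                      n_samples = config$n_samples,
                                      seed = config$seed)
        }
        t0 <- Sys.time()
        fits <- optimize_policy(channels, architecture(arch),
                                n_restarts = config$n_restarts,
                                min_iters = config$min_iters,
                                tol = config$tol, seed = config$seed)
        cell <- dplyr::bind_rows(lapply(fits, function(f) {
          lj <- build_loop_joint(f$policy, channels$sensor)
          measure_panel(lj, sensor_length = sl, architecture = arch,
                        restart = f$restart, p_g1 = f$final_p_g1,
                        n_iters = f$n_iters, converged = f$converged,
                        trace_min_delta = min(diff(f$likelihood_trace)))
        }))
        if (verbose) {
          message(sprintf("%s: best P(g1) = %.4f [%.1fs]", cell_id,
                          max(cell$p_g1),
                          as.numeric(difftime(Sys.time(), t0, units = "secs"))))
        }
        cell
      }, error = function(e) {
        failures <<- c(failures, paste0(cell_id, ": ", conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) {
        if (!is.null(out_dir)) {
          utils::write.csv(res, .lf_cell_file(out_dir, sl, arch),
                           row.names = FALSE)
        }
        rows[[cell_id]] <- res
      }
    }
  }
  if (length(failures) > 0L) {
    stop("sweep cells failed:\n", paste(failures, collapse = "\n"))
  }
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  out <- dplyr::arrange(out, .data$sensor_length, .data$architecture,
                        .data$restart)
  class(out) <- c("loop_sweep", class(out))
  attr(out, "config") <- config
  out
}

.LF_MEASURE_COLS <- c("phi_T", "psi_S", "psi_R", "psi_A", "psi_SI", "psi_C",
                      "psi_TIF")

#' Trend statistics of a sweep
#'
#' Spearman rank correlation of each measure's per-length mean (per
#' architecture) against sensor length, with the sign report for the
#' antagonism between integrated information (expected negative) and
#' morphological computation (expected positive).
#'
#' @param result A [run_sweep()] tibble (needs at least 4 sensor lengths).
#' @return A tibble with columns `architecture`, `measure`, `spearman_rho`,
#'   `direction`.
#' @export
trend_statistics <- function(result) {
  if (dplyr::n_distinct(result$sensor_length) < 4L) {
    stop("need at least 4 sensor lengths for trend statistics")
  }
  means <- result |>
    dplyr::group_by(.data$architecture, .data$sensor_length) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(c("p_g1", .LF_MEASURE_COLS)),
                                   mean), .groups = "drop")
  long <- tidyr::pivot_longer(means, dplyr::all_of(c("p_g1", .LF_MEASURE_COLS)),
                              names_to = "measure", values_to = "value")
  long |>
    dplyr::group_by(.data$architecture, .data$measure) |>
    dplyr::summarise(spearman_rho = {
      if (stats::sd(.data$value) == 0) {
        warning("constant series; Spearman correlation undefined")
        NA_real_
      } else {
        stats::cor(.data$sensor_length, .data$value, method = "spearman")
      }
    }, .groups = "drop") |>
    dplyr::mutate(direction = dplyr::case_when(
      is.na(.data$spearman_rho) ~ "flat",
      .data$spearman_rho > 0 ~ "increasing",
      .data$spearman_rho < 0 ~ "decreasing",
      TRUE ~ "flat"))
}

#' Architecture survival differences
#'
#' Per-length differences of mean survival probability between pairs of
#' architectures (positive: the first of the pair performs better).
#'
#' @param result A [run_sweep()] tibble containing at least two
#'   architectures.
#' @return A tibble with columns `sensor_length`, `comparison`,
#'   `difference`.
#' @export
goal_differences <- function(result) {
  means <- result |>
    dplyr::group_by(.data$architecture, .data$sensor_length) |>
    dplyr::summarise(p_g1 = mean(.data$p_g1), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "architecture", values_from = "p_g1")
  archs <- setdiff(names(means), "sensor_length")
  out <- list()
  for (i in seq_along(archs)) {
    for (j in seq_along(archs)) {
      if (i >= j) next
      out[[length(out) + 1L]] <- tibble::tibble(
        sensor_length = means$sensor_length,
        comparison = paste0(archs[i], " - ", archs[j]),
        difference = means[[archs[i]]] - means[[archs[j]]])
    }
  }
  dplyr::bind_rows(out)
}

#' Plot a sweep
#'
#' Line plot of per-length means (one panel per measure or survival
#' probability, coloured by architecture).
#'
#' @param object A `loop_sweep` tibble.
#' @param measures Which columns to panel (default: survival plus all
#'   seven measures).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_sweep <- function(object,
                                measures = c("p_g1", .LF_MEASURE_COLS), ...) {
  means <- object |>
    dplyr::group_by(.data$architecture, .data$sensor_length) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(measures), mean),
                     .groups = "drop")
  long <- tidyr::pivot_longer(means, dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  long$measure <- factor(long$measure, levels = measures)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sensor_length,
                                     y = .data$value,
                                     colour = .data$architecture)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "sensor length", y = "bits (p_g1: probability)") +
    ggplot2::theme_minimal()
}

#' Write the standard figure files for a sweep
#'
#' One line plot per measure (and survival) per architecture, plus the
#' architecture goal-difference plot with a zero reference line.
#'
#' @param result A `loop_sweep` tibble.
#' @param outdir Output directory (created if missing).
#' @param width,height Device size in inches.
#' @return Character vector of the files written, invisibly.
#' @export
plot_panels <- function(result, outdir, width = 5, height = 3.5) {
  if (nrow(result) == 0L) stop("empty sweep result")
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  for (m in c("p_g1", .LF_MEASURE_COLS)) {
    p <- autoplot.loop_sweep(result, measures = m) +
      ggplot2::facet_null() +
      ggplot2::labs(y = m)
    f <- file.path(outdir, paste0(m, ".png"))
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
    files <- c(files, f)
  }
  if (dplyr::n_distinct(result$architecture) > 1L) {
    gd <- goal_differences(result)
    p <- ggplot2::ggplot(gd, ggplot2::aes(x = .data$sensor_length,
                                          y = .data$difference,
                                          colour = .data$comparison)) +
      ggplot2::geom_hline(yintercept = 0, colour = "black") +
      ggplot2::geom_line() +
      ggplot2::geom_point(size = 1) +
      ggplot2::labs(x = "sensor length", y = "survival difference") +
      ggplot2::theme_minimal()
    f <- file.path(outdir, "goal_differences.png")
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
    files <- c(files, f)
  }
  invisible(files)
}
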