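# Directional grid sweep ("smart search"): for each ML translation, test
# vertical distractions from most likely to dislocate (v_max) down to least
# likely (v_min); on the first confirmed failure -- after one re-search with
# the extended budget -- record the smallest dislocating distraction as the
# DD for that ML and move on. Remaining lower levels are skipped under the
# monotonicity assumption (auditable with early_exit = FALSE).

#' Sweep grid specification
#'
#' Inclusive vertical-distraction and ML-translation ranges. The defaults
#' (0-8 mm by 0.25 vertically, 0-6 mm by 0.25 mediolaterally) give
#' 33 x 25 = 825 configurations.
#'
#' @param v_min,v_max,v_step vertical distraction range and step (mm).
#' @param ml_min,ml_max,ml_step ML translation range and step (mm).
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(v_min = 0, v_max = 8, v_step = 0.25,
                      ml_min = 0, ml_max = 6, ml_step = 0.25) {
  if (v_step <= 0 || ml_step <= 0) stop("grid steps must be positive")
  if (v_max < v_min || ml_max < ml_min) stop("grid ranges must be non-empty")
  structure(list(v_min = v_min, v_max = v_max, v_step = v_step,
                 ml_min = ml_min, ml_max = ml_max, ml_step = ml_step),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  g <- enumerate_grid(x)
  cat(sprintf("grid_spec: v %g..%g by %g, ml %g..%g by %g (%d configurations)\n",
              x$v_min, x$v_max, x$v_step, x$ml_min, x$ml_max, x$ml_step,
              nrow(g)))
  invisible(x)
}

grid_values <- function(lo, hi, step) {
  n <- floor((hi - lo) / step + 1e-9)
  lo + step * (0:n)
}

#' Enumerate the configuration grid
#'
#' @param spec a [grid_spec()].
#' @return data frame with columns `ml_mm` and `v_mm`, row-major (ML
#'   ascending, then distraction ascending within each ML).
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  ml <- grid_values(spec$ml_min, spec$ml_max, spec$ml_step)
  v <- grid_values(spec$v_min, spec$v_max, spec$v_step)
  data.frame(ml_mm = rep(ml, each = length(v)), v_mm = rep(v, length(ml)))
}

#' Directional smart sweep
#'
#' For each ML translation (ascending), vertical distractions are tested in
#' descending order. Each configuration is planned with the `initial`
#' budget; a failure is re-searched once with the `extended` budget; a
#' confirmed failure (or an invalid start, i.e. the bearing cannot be seated)
#' fixes that ML's Distraction to Dislocation (DD) as the smallest
#' distraction that dislocated, and the sweep advances to the next ML. If
#' the very first (maximum) distraction fails, DD is `NA` ("no dislocation
#' in range"); if every level down to the minimum dislocates, DD is the
#' minimum.
#'
#' @param direction dislocation direction label (see [build_scene()]).
#' @param spec a [grid_spec()].
#' @param initial,extended [planner_settings()] for the first search and the
#'   ramped-up re-search.
#' @param params an [implant_params()]; ignored when `scene_source` is given.
#' @param scene_source optional scene factory `(direction, config) -> scene`
#'   (e.g. [oracle_scene_source()]); defaults to
#'   [implant_scene_source()]`(params)`.
#' @param early_exit move to the next ML on the first confirmed failure
#'   (default). `FALSE` evaluates the full grid, auditing the monotonicity
#'   assumption; this is also the brute-force reference for planner-call
#'   counting.
#' @param max_correction,lift_step valid-start correction limits
#'   (see [find_valid_start()]).
#' @param seed master seed; every (configuration, phase, attempt) derives its
#'   own seed from it.
#' @return an object of class `sweep_result`: per-configuration `outcomes`,
#'   the per-ML `dd` table, invocation `counts` and the settings snapshot.
#' @export
smart_sweep <- function(direction, spec, initial, extended,
                        params = implant_params(), scene_source = NULL,
                        early_exit = TRUE, max_correction = 3,
                        lift_step = 0.01, seed = initial$seed) {
  stopifnot(inherits(spec, "grid_spec"),
            inherits(initial, "planner_settings"),
            inherits(extended, "planner_settings"))
  if (is.null(scene_source)) scene_source <- implant_scene_source(params)
  ml_vals <- grid_values(spec$ml_min, spec$ml_max, spec$ml_step)
  v_vals <- rev(grid_values(spec$v_min, spec$v_max, spec$v_step))  # descending
  rows <- list()
  dd <- data.frame(ml_mm = ml_vals, dd_mm = NA_real_)
  planner_calls <- 0L
  attempts_total <- 0L
  samples_total <- 0
  dislocations <- 0L
  evaluated <- 0L

  for (mi in seq_along(ml_vals)) {
    ml <- ml_vals[mi]
    last_dislocating <- NA_real_
    stopped_at <- NA_integer_
    for (vi in seq_along(v_vals)) {
      v <- v_vals[vi]
      scene <- scene_source(direction, configuration(ml, v))
      st <- find_valid_start(scene, max_correction = max_correction,
                             lift_step = lift_step)
      evaluated <- evaluated + 1L
      if (is.null(st)) {
        rows[[length(rows) + 1L]] <- data.frame(
          direction = direction, ml_mm = ml, v_mm = v,
          outcome = "invalid_start", phase = NA_character_,
          attempts_used = 0L, samples_drawn = 0)
        failed <- TRUE
      } else {
        scene$start <- st
        s1 <- initial
        s1$seed <- derive_seed(seed, mi, vi, 1L)
        r <- plan_with_attempts(scene, s1)
        planner_calls <- planner_calls + 1L
        phase <- "initial"
        if (r$status == "no_path_within_budget") {
          s2 <- extended
          s2$seed <- derive_seed(seed, mi, vi, 2L)
          r2 <- plan_with_attempts(scene, s2)
          planner_calls <- planner_calls + 1L
          r2$attempts_used <- r2$attempts_used + r$attempts_used
          r2$samples_drawn <- r2$samples_drawn + r$samples_drawn
          r <- r2
          phase <- "extended"
        }
        attempts_total <- attempts_total + r$attempts_used
        samples_total <- samples_total + r$samples_drawn
        outcome <- if (r$status == "dislocated") "dislocated" else
          if (r$status == "invalid_start") "invalid_start" else "no_dislocation"
        rows[[length(rows) + 1L]] <- data.frame(
          direction = direction, ml_mm = ml, v_mm = v, outcome = outcome,
          phase = phase, attempts_used = r$attempts_used,
          samples_drawn = r$samples_drawn)
        failed <- outcome != "dislocated"
      }
      if (!failed) {
        dislocations <- dislocations + 1L
        last_dislocating <- v
      } else if (early_exit) {
        stopped_at <- vi
        break
      }
    }
    if (early_exit) {
      dd$dd_mm[mi] <- last_dislocating
      if (!is.na(stopped_at) && stopped_at < length(v_vals)) {
        skip_v <- v_vals[(stopped_at + 1L):length(v_vals)]
        rows[[length(rows) + 1L]] <- data.frame(
          direction = direction, ml_mm = ml, v_mm = skip_v,
          outcome = "skipped", phase = NA_character_, attempts_used = 0L,
          samples_drawn = 0)
      }
    } else {
      # audit mode: DD is the bottom of the contiguous dislocated run from
      # the top of the range
      col <- vapply(rows, function(r) r$ml_mm[1] == ml, logical(1))
      out <- do.call(rbind, rows[col])
      out <- out[order(-out$v_mm), ]
      run <- cumprod(out$outcome == "dislocated") > 0
      dd$dd_mm[mi] <- if (any(run)) min(out$v_mm[run]) else NA_real_
    }
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  structure(list(direction = direction, outcomes = outcomes, dd = dd,
                 counts = list(planner_calls = planner_calls,
                               attempts_total = attempts_total,
                               samples_total = samples_total,
                               configurations_evaluated = evaluated,
                               dislocations = dislocations),
                 grid = spec,
                 settings = list(initial = initial, extended = extended),
                 seed = seed, early_exit = early_exit),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf(
    "sweep_result (%s): %d configurations evaluated, %d dislocations, %d planner calls\n",
    x$direction, x$counts$configurations_evaluated, x$counts$dislocations,
    x$counts$planner_calls))
  print(x$dd, row.names = FALSE)
  invisible(x)
}

#' Maximum theoretical testing time, brute force
#'
#' Every configuration searched at the full budget:
#' `n_configs * time_s * attempts` seconds.
#'
#' @param n_configs number of configurations.
#' @param time_s search time per attempt (s).
#' @param attempts search attempts per configuration.
#' @return seconds.
#' @export
theoretical_max_time <- function(n_configs, time_s, attempts) {
  n_configs * time_s * attempts
}

#' Maximum theoretical testing time, smart search
#'
#' With directional searching, only the dislocating configurations (minus the
#' final one per ML column) are searched at the initial budget, and one
#' confirmed failure per ML column runs at the extended budget:
#' `(n_dislocations - n_ml) * t_init * a_init + n_ml * t_ext * a_ext`.
#'
#' @param n_dislocations total dislocating configurations found.
#' @param n_ml number of ML translation values tested.
#' @param t_init,a_init initial search time (s) and attempts.
#' @param t_ext,a_ext extended search time (s) and attempts.
#' @return seconds.
#' @export
optimised_max_time <- function(n_dislocations, n_ml, t_init, a_init, t_ext,
                               a_ext) {
  (n_dislocations - n_ml) * t_init * a_init + n_ml * t_ext * a_ext
}

#' Write sweep results to CSV
#'
#' Writes a per-configuration detail file (`<prefix>_configurations.csv`:
#' direction, ml_mm, v_mm, outcome, phase, attempts_used, samples_drawn) and
#' a per-ML summary (`<prefix>_summary.csv`: direction, ml_mm, dd_mm).
#'
#' @param result a [smart_sweep()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; defaults to the direction.
#' @return named character vector of the two paths, invisibly.
#' @export
write_sweep_csv <- function(result, dir, prefix = result$direction) {
  stopifnot(inherits(result, "sweep_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  detail <- file.path(dir, paste0(prefix, "_configurations.csv"))
  summary <- file.path(dir, paste0(prefix, "_summary.csv"))
  utils::write.csv(result$outcomes, detail, row.names = FALSE)
  s <- cbind(direction = result$direction, result$dd)
  utils::write.csv(s, summary, row.names = FALSE)
  invisible(c(detail = detail, summary = summary))
}

#' Read a sweep summary CSV
#'
#' @param path a summary file written by [write_sweep_csv()] (or an external
#'   rig-measurement table with the same columns: `ml_mm`, `dd_mm` and
#'   optionally `direction`).
#' @return data frame.
#' @export
read_sweep_summary <- function(path) {
  df <- utils::read.csv(path)
  need <- c("ml_mm", "dd_mm")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("summary '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  df
}

#' Plot DD against ML translation
#'
#' One panel per direction: the DD curve with the dislocation zone (at or
#' above the curve) shaded grey; MLs with no dislocation in range are left
#' unshaded.
#'
#' @param summary data frame with columns `direction`, `ml_mm`, `dd_mm`
#'   (e.g. from [read_sweep_summary()] or `sweep_result$dd`).
#' @param v_max top of the tested distraction range (mm), for the shading.
#' @param file optional PNG path; `NULL` draws to the active device.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_dd <- function(summary, v_max = 8, file = NULL) {
  dirs <- unique(summary$direction)
  if (!is.null(file)) {
    grDevices::png(file, width = 480 * length(dirs), height = 480, res = 96)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(1, length(dirs)), mar = c(4, 4, 2, 1))
  # the file device is closed wholesale; only restore par on a live device
  if (is.null(file)) on.exit(graphics::par(op), add = TRUE)
  for (d in dirs) {
    s <- summary[summary$direction == d, ]
    s <- s[order(s$ml_mm), ]
    graphics::plot(s$ml_mm, s$dd_mm, type = "n", ylim = c(0, v_max),
                   xlab = "ML translation (mm)",
                   ylab = "Distraction to Dislocation (mm)", main = d)
    ok <- !is.na(s$dd_mm)
    if (any(ok)) {
      graphics::polygon(c(s$ml_mm[ok], rev(s$ml_mm[ok])),
                        c(s$dd_mm[ok], rep(v_max, sum(ok))),
                        col = "grey85", border = NA)
      graphics::lines(s$ml_mm[ok], s$dd_mm[ok], lwd = 2)
      graphics::points(s$ml_mm[ok], s$dd_mm[ok], pch = 16)
    }
  }
  invisible(file)
}
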