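#' Experiment design specification
#'
#' Describes the factorial layout of a prospective time-estimation session:
#' every participant performs, in each motor condition, `reps_per_cell` trials
#' of every (cognitive task, nominal interval) combination. Trials are grouped
#' into blocks in which every nominal interval occurs exactly twice, so that
#' blocks have roughly equal wall-clock duration; tasks are interleaved at
#' random within that constraint. Actual trial durations are jittered integers
#' within +/- `jitter_fraction` of the nominal interval, which discourages
#' counting strategies keyed to a fixed set of durations.
#'
#' @param n_participants Number of participants.
#' @param tasks Character vector of cognitive task labels, ordered by nominal
#'   difficulty. Defaults to `look`, `read`, `solve_simple`, `solve_hard`.
#' @param conditions Character vector of motor conditions.
#' @param nominal_intervals Nominal interval midpoints in seconds.
#' @param reps_per_cell Trials per (task, interval) cell per condition.
#' @param jitter_fraction Half-width of the duration jitter window as a
#'   fraction of the nominal interval (default 0.10).
#' @param block_size Trials per block; must equal `2 * length(nominal_intervals)`
#'   so each block can contain every interval exactly twice.
#' @param rng_seed Integer seed making [generate_design()] deterministic.
#'
#' @return An object of class `design_spec` (a named list).
#' @seealso [generate_design()]
#' @export
#' @examples
#' spec <- design_spec(n_participants = 2)
#' trials <- generate_design(spec)
#' nrow(trials)  # 2 participants x 2 conditions x 200 trials
design_spec <- function(n_participants = 16,
                        tasks = c("look", "read", "solve_simple", "solve_hard"),
                        conditions = c("sitting", "walking"),
                        nominal_intervals = c(15, 30, 60, 90, 120),
                        reps_per_cell = 10,
                        jitter_fraction = 0.10,
                        block_size = 10,
                        rng_seed = 1L) {
  stopifnot(
    n_participants >= 1,
    length(tasks) >= 1, !anyDuplicated(tasks),
    length(conditions) >= 1, !anyDuplicated(conditions),
    length(nominal_intervals) >= 1, all(nominal_intervals > 0),
    reps_per_cell >= 1,
    jitter_fraction >= 0, jitter_fraction < 1
  )
  if (block_size != 2L * length(nominal_intervals)) {
    stop("`block_size` must equal 2 * length(nominal_intervals) (",
         2L * length(nominal_intervals),
         ") so that every block contains each interval exactly twice.",
         call. = FALSE)
  }
  if ((length(tasks) * reps_per_cell) %% 2L != 0L) {
    stop("length(tasks) * reps_per_cell must be even to fill blocks that ",
         "contain each interval twice.", call. = FALSE)
  }
  structure(
    list(
      n_participants = as.integer(n_participants),
      tasks = tasks,
      conditions = conditions,
      nominal_intervals = as.numeric(nominal_intervals),
      reps_per_cell = as.integer(reps_per_cell),
      jitter_fraction = jitter_fraction,
      block_size = as.integer(block_size),
      rng_seed = as.integer(rng_seed)
    ),
    class = "design_spec"
  )
}

#' Integer jitter window of a nominal interval
#'
#' The support of actual durations for a nominal interval `T` is the set of
#' integers spanning `[floor((1 - f) * T), ceiling((1 + f) * T)]`, e.g. for
#' 15 s and f = 0.10 the values 13, 14, 15, 16, 17.
#'
#' @param nominal Nominal interval in seconds.
#' @param jitter_fraction Fractional half-width (default 0.10).
#' @return Integer vector of admissible actual durations.
#' @export
#' @examples
#' jitter_window(15)   # 13:17
#' jitter_window(120)  # 108:132
jitter_window <- function(nominal, jitter_fraction = 0.10) {
  stopifnot(length(nominal) == 1, nominal > 0)
  b <- window_bounds(nominal, jitter_fraction)
  seq.int(b[1], b[2])
}

# floor/ceiling with a fuzz so 1.1 * 90 = 99.000...01 stays 99
window_bounds <- function(nominal, jitter_fraction) {
  eps <- 1e-8 * nominal
  c(floor((1 - jitter_fraction) * nominal + eps),
    ceiling((1 + jitter_fraction) * nominal - eps))
}

#' Generate the trial table of an experiment design
#'
#' Produces one row per trial with participant, motor condition, session,
#' block, task, nominal interval and a jittered integer actual duration.
#' Estimates are left as `NA`; feed the result to [linear_clock_model()] or
#' [pacemaker_accumulator_model()] to simulate responses. Within every
#' participant x condition, each nominal interval appears exactly twice per
#' block and each (task, interval) cell exactly `reps_per_cell` times overall;
#' tasks are interleaved uniformly at random subject to those quotas. Blocks
#' are split evenly across two sessions (the `session` column), mirroring a
#' two-visit protocol per motor condition.
#'
#' @param spec A [design_spec()].
#' @return A tibble with columns `participant_id`, `condition`, `session`,
#'   `block`, `task`, `nominal_s`, `actual_s`, `estimate_s` (all `NA`).
#' @export
generate_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  n_blocks <- (length(spec$tasks) * spec$reps_per_cell) %/% 2L
  windows <- lapply(spec$nominal_intervals, jitter_window,
                    jitter_fraction = spec$jitter_fraction)
  names(windows) <- as.character(spec$nominal_intervals)
  ids <- sprintf("p%02d", seq_len(spec$n_participants))

  withr::with_seed(spec$rng_seed, {
    per_unit <- function(pid, cond) {
      # For each interval: reps_per_cell copies of every task, shuffled, then
      # dealt two per block -> each block holds every interval exactly twice.
      rows <- lapply(seq_along(spec$nominal_intervals), function(i) {
        task_seq <- sample(rep(spec$tasks, spec$reps_per_cell))
        tibble::tibble(
          block = rep(seq_len(n_blocks), each = 2L),
          task = task_seq,
          nominal_s = spec$nominal_intervals[i],
          actual_s = sample(windows[[i]], 2L * n_blocks, replace = TRUE)
        )
      })
      unit <- dplyr::bind_rows(rows)
      # shuffle trial order within each block
      unit <- unit[order(unit$block, sample.int(nrow(unit))), ]
      unit$participant_id <- pid
      unit$condition <- cond
      unit$session <- ifelse(unit$block <= ceiling(n_blocks / 2), 1L, 2L)
      unit
    }
    grid <- expand.grid(pid = ids, cond = spec$conditions,
                        stringsAsFactors = FALSE)
    out <- dplyr::bind_rows(Map(per_unit, grid$pid, grid$cond))
    out$estimate_s <- NA_real_
    tibble::as_tibble(out[, c("participant_id", "condition", "session",
                              "block", "task", "nominal_s", "actual_s",
                              "estimate_s")])
  })
}

#' Generate a treadmill speed schedule
#'
#' Walking blocks use an irregular speed profile so that participants cannot
#' pace-count: speeds stay within 1.4--3.0 km/h, successive changes have
#' magnitude 0.4--1.6 km/h, and changes occur every 20--40 s. The schedule is
#' session metadata only; it does not enter the response models.
#'
#' @param total_duration Schedule length in seconds.
#' @param seed Integer seed.
#' @param speed_range Admissible speed band in km/h.
#' @param change_range Admissible absolute speed-change band in km/h.
#' @param interval_range Admissible time between changes in seconds.
#' @return A tibble with columns `onset_s` and `speed_kmh`; zero rows when
#'   `total_duration` is 0.
#' @export
generate_speed_schedule <- function(total_duration,
                                    seed = 1L,
                                    speed_range = c(1.4, 3.0),
                                    change_range = c(0.4, 1.6),
                                    interval_range = c(20, 40)) {
  stopifnot(total_duration >= 0, speed_range[1] < speed_range[2],
            change_range[1] > 0, change_range[1] <= change_range[2],
            interval_range[1] > 0, interval_range[1] <= interval_range[2])
  if (total_duration == 0) {
    return(tibble::tibble(onset_s = numeric(), speed_kmh = numeric()))
  }
  withr::with_seed(seed, {
    onsets <- 0
    speeds <- runif(1, speed_range[1], speed_range[2])
    t <- runif(1, interval_range[1], interval_range[2])
    while (t < total_duration) {
      s <- speeds[length(speeds)]
      # feasible change magnitudes in each direction, staying inside the band
      up_max <- min(change_range[2], speed_range[2] - s)
      dn_max <- min(change_range[2], s - speed_range[1])
      dirs <- c(if (up_max >= change_range[1]) 1, if (dn_max >= change_range[1]) -1)
      dir <- if (length(dirs) == 1) dirs else sample(dirs, 1)
      dmax <- if (dir > 0) up_max else dn_max
      delta <- runif(1, change_range[1], dmax)
      speeds <- c(speeds, s + dir * delta)
      onsets <- c(onsets, t)
      t <- t + runif(1, interval_range[1], interval_range[2])
    }
    tibble::tibble(onset_s = onsets, speed_kmh = speeds)
  })
}
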