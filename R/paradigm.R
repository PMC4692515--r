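#' Define a blocked motion-imagery paradigm
#'
#' Describes the timing of a blocked four-direction imagery experiment:
#' `n_runs` runs of `blocks_per_run` blocks, each block presenting every
#' direction condition exactly once in random order. Trials last 6 or 8 s,
#' blocks are separated by jittered rests of 8, 10 or 12 s, and every
#' duration is an integer multiple of the volume repetition time `tr_s`.
#'
#' @param tr_s Volume repetition time in seconds.
#' @param n_runs Number of runs (leave-one-run-out decoding needs at least 2;
#'   a single run is allowed for event generation alone).
#' @param blocks_per_run Blocks per run.
#' @param trials_per_block Trials per block; must equal the number of
#'   conditions so each block contains each condition once.
#' @param conditions Integer condition labels (default `1:4`).
#' @param condition_angles_deg Motion direction (degrees, counterclockwise
#'   from rightward) associated with each condition.
#' @param trial_durations_s Allowed trial durations; drawn equiprobably.
#' @param inter_block_rests_s Allowed rest durations after each block
#'   (the post-block rating period is folded into the rest); drawn
#'   equiprobably.
#' @param pre_block_rest_s Rest before the first block of each run.
#' @param seed Integer seed controlling all paradigm randomness.
#' @return An object of class `paradigm_spec`.
#' @examples
#' spec <- paradigm_spec()
#' ev <- generate_events(spec)
#' table(ev$condition)
#' @export
paradigm_spec <- function(tr_s = 2, n_runs = 4, blocks_per_run = 10,
                          trials_per_block = 4, conditions = 1:4,
                          condition_angles_deg = c(0, 90, 180, 270),
                          trial_durations_s = c(6, 8),
                          inter_block_rests_s = c(8, 10, 12),
                          pre_block_rest_s = 12, seed = 1L) {
  if (!is_count(n_runs, 1L)) stop("n_runs must be a positive integer")
  if (!is_count(blocks_per_run, 1L)) stop("blocks_per_run must be a positive integer")
  if (trials_per_block != length(conditions))
    stop("trials_per_block must equal the number of conditions")
  if (length(condition_angles_deg) != length(conditions))
    stop("one angle per condition is required")
  if (tr_s <= 0) stop("tr_s must be positive")
  durs <- c(trial_durations_s, inter_block_rests_s, pre_block_rest_s)
  if (any(abs(durs / tr_s - round(durs / tr_s)) > 1e-9))
    stop("all durations must be integer multiples of tr_s")
  structure(list(
    tr_s = tr_s, n_runs = as.integer(n_runs),
    blocks_per_run = as.integer(blocks_per_run),
    trials_per_block = as.integer(trials_per_block),
    conditions = as.integer(conditions),
    condition_angles_deg = condition_angles_deg,
    trial_durations_s = trial_durations_s,
    inter_block_rests_s = inter_block_rests_s,
    pre_block_rest_s = pre_block_rest_s,
    seed = as.integer(seed)
  ), class = "paradigm_spec")
}

#' @export
print.paradigm_spec <- function(x, ...) {
  cat("Blocked imagery paradigm:", x$n_runs, "runs x", x$blocks_per_run,
      "blocks x", x$trials_per_block, "trials; TR =", x$tr_s, "s\n")
  cat("  conditions:", paste(x$conditions, collapse = ", "),
      " angles:", paste(x$condition_angles_deg, collapse = ", "), "deg\n")
  invisible(x)
}

#' Generate the trial event table for a paradigm
#'
#' Lays out every run: an initial rest, then blocks of back-to-back trials
#' (one trial per condition, order randomly permuted per block) each followed
#' by a jittered rest. Trial durations and rests are drawn equiprobably from
#' the sets in the spec. All onsets fall on the volume grid.
#'
#' @param spec A [paradigm_spec()].
#' @return A `data.frame` of class `event_table` with columns `run`
#'   (1-based), `onset` (seconds from run start), `duration` (seconds) and
#'   `condition`, plus attributes `tr_s`, `n_volumes` (volumes per run) and
#'   `condition_angles_deg`.
#' @export
generate_events <- function(spec) {
  stopifnot(inherits(spec, "paradigm_spec"))
  with_seed(derive_seed(spec$seed, "events"), {
    rows <- vector("list", spec$n_runs)
    n_volumes <- integer(spec$n_runs)
    for (r in seq_len(spec$n_runs)) {
      t <- spec$pre_block_rest_s
      run_rows <- list()
      for (b in seq_len(spec$blocks_per_run)) {
        conds <- sample(spec$conditions)
        for (cc in conds) {
          dur <- if (length(spec$trial_durations_s) > 1L)
            sample(spec$trial_durations_s, 1L) else spec$trial_durations_s
          run_rows[[length(run_rows) + 1L]] <-
            data.frame(run = r, onset = t, duration = dur, condition = cc)
          t <- t + dur
        }
        rest <- if (length(spec$inter_block_rests_s) > 1L)
          sample(spec$inter_block_rests_s, 1L) else spec$inter_block_rests_s
        t <- t + rest
      }
      rows[[r]] <- do.call(rbind, run_rows)
      n_volumes[r] <- as.integer(round(t / spec$tr_s))
    }
    ev <- do.call(rbind, rows)
    rownames(ev) <- NULL
    structure(ev,
              tr_s = spec$tr_s, n_volumes = n_volumes,
              condition_angles_deg = stats::setNames(
                spec$condition_angles_deg, spec$conditions),
              class = c("event_table", "data.frame"))
  })
}

#' Write / read an event table as tab-separated text
#'
#' The on-disk format has a header line `run onset duration condition`
#' with seconds for onsets/durations and 1-based run indices.
#'
#' @param events An `event_table`.
#' @param path File path.
#' @param tr_s,n_volumes Timing metadata restored onto the read table
#'   (optional for [read_events()]).
#' @return `read_events` returns an `event_table`; `write_events` returns
#'   `path` invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events)[, c("run", "onset", "duration", "condition")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, tr_s = 2, n_volumes = NULL) {
  ev <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("run", "onset", "duration", "condition") %in% names(ev)))
  validate_events(ev)
  structure(ev, tr_s = tr_s, n_volumes = n_volumes,
            class = c("event_table", "data.frame"))
}

validate_events <- function(ev) {
  for (r in unique(ev$run)) {
    e <- ev[ev$run == r, ]
    e <- e[order(e$onset), ]
    if (nrow(e) > 1L && any(e$onset[-1L] < (e$onset + e$duration)[-nrow(e)] - 1e-9))
      stop("overlapping trials in run ", r)
  }
  invisible(ev)
}

# volumes per run implied by an event table (last trial end + padding)
events_n_volumes <- function(events, tr_s = attr(events, "tr_s")) {
  nv <- attr(events, "n_volumes")
  if (!is.null(nv)) return(nv)
  vapply(sort(unique(events$run)), function(r) {
    e <- events[events$run == r, ]
    as.integer(ceiling((max(e$onset + e$duration) + 12) / tr_s))
  }, integer(1L))
}
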