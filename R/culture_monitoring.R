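# Longitudinal monitoring of primary cultures.
#
# Each sample is split into two media arms (ABM, NSM) and followed by ddPCR
# at up to four stages: p0 (initial dissociated suspension), p1 (after ~1
# week in culture), transduced (first passage after successful SV40-TAg
# infection) and final (latest measurement). Milestones form the swimmer
# plot chain: viable at p1 -> transduced -> line established.

STAGE_LEVELS <- c("P0", "P1", "TRANSDUCED", "FINAL")
MEDIUM_LEVELS <- c("ABM", "NSM", "NONE")

#' Construct a culture timepoint
#'
#' @param stage One of `"P0"`, `"P1"`, `"TRANSDUCED"`, `"FINAL"`.
#' @param passage_index Passage number, `>= 0`.
#' @param medium `"ABM"`, `"NSM"`, or `"NONE"` (the initial suspension, which
#'   precedes the media split, carries `"NONE"`).
#' @param tcf TCF in `[0, 1]`, or `NA` when gDNA could not be collected.
#' @return One-row tibble.
#' @export
culture_timepoint <- function(stage, passage_index = 0L, medium = "NONE",
                              tcf = NA_real_) {
  stage <- match.arg(stage, STAGE_LEVELS)
  medium <- match.arg(medium, MEDIUM_LEVELS)
  if (passage_index < 0) {
    abort("passage_index must be >= 0", class = "plgg_validation_error")
  }
  if (inherits(tcf, "tcf_estimate")) tcf <- tcf$tcf
  if (!is.na(tcf) && (tcf < 0 || tcf > 1)) {
    abort("tcf must lie in [0, 1]", class = "plgg_validation_error")
  }
  tibble(stage = stage, passage_index = as.integer(passage_index),
         medium = medium, tcf = as.numeric(tcf))
}

#' Assemble a culture trajectory
#'
#' Orders timepoints by stage (P0 < P1 < TRANSDUCED < FINAL) and derives
#' the milestone chain: `viable_at_p1` when a P1 timepoint exists,
#' `transduced` when a TRANSDUCED timepoint exists. `line_established`
#' stays `NA` until [classify_outcome()] is applied.
#'
#' @param sample_id Sample identifier.
#' @param medium `"ABM"` or `"NSM"` — trajectories are keyed by
#'   (sample, medium) because every sample is split into both arms.
#' @param timepoints Tibble of timepoints (rows from [culture_timepoint()]),
#'   at most one per stage.
#' @return Object of class `"culture_trajectory"`.
#' @export
build_trajectory <- function(sample_id, medium = c("ABM", "NSM"), timepoints) {
  medium <- match.arg(medium)
  if (anyDuplicated(timepoints$stage)) {
    abort(paste0("duplicate stage in trajectory for ", sample_id, "/", medium),
          class = "plgg_validation_error")
  }
  ord <- order(match(timepoints$stage, STAGE_LEVELS))
  timepoints <- timepoints[ord, ]
  structure(list(
    sample_id = sample_id,
    medium = medium,
    timepoints = timepoints,
    milestones = list(
      viable_at_p1 = "P1" %in% timepoints$stage,
      transduced = "TRANSDUCED" %in% timepoints$stage,
      line_established = NA
    )
  ), class = "culture_trajectory")
}

#' @export
print.culture_trajectory <- function(x, ...) {
  cat("Trajectory ", x$sample_id, " [", x$medium, "]: ",
      paste(sprintf("%s=%s", x$timepoints$stage,
                    ifelse(is.na(x$timepoints$tcf), "NA",
                           sprintf("%.0f%%", 100 * x$timepoints$tcf))),
            collapse = " -> "), "\n", sep = "")
  m <- x$milestones
  cat("  viable at p1: ", m$viable_at_p1, "; transduced: ", m$transduced,
      "; established: ", m$line_established, "\n", sep = "")
  invisible(x)
}

#' Relative change in TCF between two timepoints
#'
#' `(tcf_p1 - tcf_p0) / tcf_p0`: the change from baseline expressed as a
#' fraction of baseline, the quantity correlated with patient age across
#' samples.
#'
#' @param tcf_p0 Baseline TCF, `> 0`.
#' @param tcf_p1 Later TCF.
#' @return Relative change (0 = unchanged, +1 = doubled, -0.5 = halved).
#' @export
relative_change <- function(tcf_p0, tcf_p1) {
  if (any(is.na(tcf_p0)) || any(tcf_p0 <= 0)) {
    abort("relative change is undefined at baseline TCF = 0",
          class = "plgg_validation_error")
  }
  (tcf_p1 - tcf_p0) / tcf_p0
}

#' Classify the outcome of a culture trajectory
#'
#' Primary pLGG cultures evolve to one of two terminal states: tumor cells
#' take over (TCF reaches 100%; a long-term line is established) or the
#' microenvironmental cells outgrow them (TCF reaches 0%; failed).
#' Classification depends only on the FINAL TCF: `ESTABLISHED` at or above
#' the success threshold, `FAILED` at or below the failure threshold,
#' `INDETERMINATE` between. Untransduced cultures never proliferate
#' long-term and cannot be classified as established, so a transduction
#' milestone is a precondition.
#'
#' @param traj A classified-ready [build_trajectory()] with a FINAL
#'   timepoint carrying a TCF and `transduced = TRUE`.
#' @param success_threshold FINAL TCF at or above which the line counts as
#'   established (default 0.95; the terminal state is nominally 100% but
#'   measurement noise requires a band).
#' @param failure_threshold FINAL TCF at or below which the culture counts
#'   as failed (default 0.05).
#' @return Object of class `"outcome_call"`: `outcome`, `final_tcf`,
#'   `rationale`; `traj`'s milestone `line_established` is set in the
#'   returned `$trajectory`.
#' @export
classify_outcome <- function(traj, success_threshold = 0.95,
                             failure_threshold = 0.05) {
  stopifnot(failure_threshold >= 0, success_threshold <= 1,
            failure_threshold < success_threshold)
  fin <- traj$timepoints[traj$timepoints$stage == "FINAL", ]
  if (nrow(fin) == 0 || is.na(fin$tcf)) {
    abort(paste0("trajectory ", traj$sample_id, "/", traj$medium,
                 " has no FINAL TCF measurement"),
          class = "plgg_validation_error")
  }
  if (!isTRUE(traj$milestones$transduced)) {
    abort(paste0("trajectory ", traj$sample_id, "/", traj$medium,
                 " was not transduced; untransduced cultures senesce and are",
                 " never classified as established"),
          class = "plgg_validation_error")
  }
  final_tcf <- fin$tcf
  outcome <- if (final_tcf >= success_threshold) "ESTABLISHED"
  else if (final_tcf <= failure_threshold) "FAILED"
  else "INDETERMINATE"
  traj$milestones$line_established <- outcome == "ESTABLISHED"
  structure(list(
    outcome = outcome,
    final_tcf = final_tcf,
    rationale = sprintf(
      "final TCF %.1f%% vs thresholds [%.0f%%, %.0f%%]",
      100 * final_tcf, 100 * failure_threshold, 100 * success_threshold),
    trajectory = traj
  ), class = "outcome_call")
}

#' @export
print.outcome_call <- function(x, ...) {
  cat(x$trajectory$sample_id, "/", x$trajectory$medium, ": ", x$outcome,
      " (", x$rationale, ")\n", sep = "")
  invisible(x)
}

#' Milestone (swimmer-plot) table
#'
#' One row per (sample, medium) with the three milestones; aggregate counts
#' (samples viable at p1, transduced, lines established) follow by summing
#' columns. Unclassified trajectories carry `line_established = FALSE`
#' when untransduced (they can never establish) and `NA` otherwise.
#'
#' @param trajectories List of `culture_trajectory` objects, classified
#'   where possible.
#' @return Tibble: `sample_id, medium, viable_at_p1, transduced,
#'   line_established`.
#' @export
milestone_table <- function(trajectories) {
  if (length(trajectories) == 0) {
    return(tibble(sample_id = character(), medium = character(),
                  viable_at_p1 = logical(), transduced = logical(),
                  line_established = logical()))
  }
  dplyr::bind_rows(lapply(trajectories, function(tr) {
    if (inherits(tr, "outcome_call")) tr <- tr$trajectory
    m <- tr$milestones
    established <- m$line_established
    if (is.na(established) && !isTRUE(m$transduced)) established <- FALSE
    tibble(sample_id = tr$sample_id, medium = tr$medium,
           viable_at_p1 = m$viable_at_p1, transduced = m$transduced,
           line_established = established)
  }))
}

#' Read longitudinal TCF measurements
#'
#' Schema: `sample_id, medium, stage, passage_index, tcf` (TCF as a
#' fraction in `[0, 1]`; empty/NA when gDNA was not collectable). Rows are
#' grouped into one trajectory per (sample, medium).
#'
#' @param path CSV path.
#' @return List of `culture_trajectory` objects.
#' @export
read_longitudinal <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("longitudinal file not found: ", path),
          class = "plgg_io_error")
  }
  raw <- suppressWarnings(readr::read_csv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    medium = readr::col_character(),
    stage = readr::col_character(),
    passage_index = readr::col_integer(),
    tcf = readr::col_double()
  ), progress = FALSE))
  needed <- c("sample_id", "medium", "stage", "passage_index", "tcf")
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0) {
    abort(paste0("longitudinal file is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "plgg_schema_error")
  }
  keys <- unique(raw[, c("sample_id", "medium")])
  lapply(seq_len(nrow(keys)), function(i) {
    rows <- raw[raw$sample_id == keys$sample_id[i] &
                  raw$medium == keys$medium[i], ]
    tps <- dplyr::bind_rows(lapply(seq_len(nrow(rows)), function(j) {
      culture_timepoint(rows$stage[j], rows$passage_index[j],
                        medium = if (rows$stage[j] == "P0") "NONE"
                        else rows$medium[j],
                        tcf = rows$tcf[j])
    }))
    build_trajectory(keys$sample_id[i], keys$medium[i], tps)
  })
}

#' Write longitudinal TCF measurements
#'
#' @param trajectories List of `culture_trajectory` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_longitudinal <- function(trajectories, path) {
  rows <- dplyr::bind_rows(lapply(trajectories, function(tr) {
    tibble(sample_id = tr$sample_id, medium = tr$medium,
           stage = tr$timepoints$stage,
           passage_index = tr$timepoints$passage_index,
           tcf = tr$timepoints$tcf)
  }))
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}
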