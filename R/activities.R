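# Activity taxonomy, node placements and sensor-combination codes.

#' Activity codes
#'
#' Nine scripted activities: six falls (F1-F6) and three fall-like
#' movements (FL1-FL3) used as the negative-class stress test.
#'
#' \describe{
#'   \item{F1}{forward fall using the knees (knee contact before impact)}
#'   \item{F2}{forward fall using the hands}
#'   \item{F3}{inclined fall to the left}
#'   \item{F4}{inclined fall to the right}
#'   \item{F5}{slow forward fall with a crouch first}
#'   \item{F6}{backward fall (seat contact before lying)}
#'   \item{FL1}{crouch}
#'   \item{FL2}{walk with a stoop}
#'   \item{FL3}{sit}
#' }
#'
#' @return character vector of the nine activity codes.
#' @export
activity_codes <- function() {
  c("F1", "F2", "F3", "F4", "F5", "F6", "FL1", "FL2", "FL3")
}

#' @rdname activity_codes
#' @param activity character vector of activity codes.
#' @return logical: TRUE for fall activities (F1-F6).
#' @export
is_fall_activity <- function(activity) {
  stopifnot(all(activity %in% activity_codes()))
  activity %in% c("F1", "F2", "F3", "F4", "F5", "F6")
}

#' Default per-subject trial counts
#'
#' The study protocol records, for each subject, 5 trials of F1 and F2,
#' 4 of F3, F4, FL1 and FL2, and 3 of F5, F6 and FL3 (35 trials per
#' subject; 490 over 14 subjects).
#'
#' @return named integer vector, one entry per activity code.
#' @export
default_trial_counts <- function() {
  c(F1 = 5L, F2 = 5L, F3 = 4L, F4 = 4L, F5 = 3L, F6 = 3L,
    FL1 = 4L, FL2 = 4L, FL3 = 3L)
}

#' IMU node placements
#'
#' The nine body placements: chest (1), elbows (2), wrists (2),
#' thighs (2) and ankles (2).
#'
#' @return character vector of the nine node identifiers.
#' @export
node_ids <- function() {
  c("chest", "elbow_l", "elbow_r", "wrist_l", "wrist_r",
    "thigh_l", "thigh_r", "ankle_l", "ankle_r")
}

# placement letter -> node ids
.placement_map <- list(
  C = "chest",
  E = c("elbow_l", "elbow_r"),
  W = c("wrist_l", "wrist_r"),
  T = c("thigh_l", "thigh_r"),
  A = c("ankle_l", "ankle_r")
)

#' Sensor-combination codes
#'
#' A combination code is a string over the alphabet C (chest), E
#' (elbows), W (wrists), T (thighs), A (ankles), each letter at most
#' once. \code{combination_nodes} expands a code to its node ids;
#' \code{imu_quantity} counts physical IMUs (1 for C, 2 for each of
#' E/W/T/A).
#'
#' @param code character scalar combination code, e.g. "CEW".
#' @return \code{combination_nodes}: character vector of node ids.
#' @export
combination_nodes <- function(code) {
  letters_ <- validate_combination(code)
  unlist(.placement_map[letters_], use.names = FALSE)
}

#' @rdname combination_nodes
#' @export
imu_quantity <- function(code) {
  letters_ <- validate_combination(code)
  sum(ifelse(letters_ == "C", 1L, 2L))
}

validate_combination <- function(code) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  letters_ <- strsplit(code, "")[[1]]
  bad <- setdiff(letters_, c("C", "E", "W", "T", "A"))
  if (length(bad)) {
    stop("invalid placement letter(s) in combination '", code, "': ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(letters_)) {
    stop("combination '", code, "' repeats a placement letter")
  }
  letters_
}

#' The 30 standard placement combinations for the ablation study
#'
#' The ablation protocol evaluates 30 of the 31 non-empty subsets of
#' \{C, E, W, T, A\} (the subset CTA is not part of the standard list).
#' Set \code{all = TRUE} to get all 31.
#'
#' @param all logical; include the 31st subset (CTA)?
#' @return character vector of combination codes.
#' @export
ablation_combinations <- function(all = FALSE) {
  codes <- c(
    "CEWTA",
    "CEWT", "CEWA", "CETA", "CWTA", "EWTA",
    "CEW", "CEA", "CWT", "EWA", "EWT", "CWA", "CET", "ETA", "WTA",
    "CE", "CW", "CT", "CA", "TA", "ET", "EA", "WT", "WA", "EW",
    "E", "W", "T", "A", "C")
  if (all) codes <- c(codes, "CTA")
  codes
}
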