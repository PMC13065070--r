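# Time-use diary model: one person-day is 144 ten-minute slots running from
# 04:00 to 04:00 the next day (slot k covers [04:00 + 10k, 04:00 + 10(k+1)),
# 0-based).  Slot activity codes are recoded through a total activity->set
# mapping into six mutually exclusive behaviour sets on weekdays (sleep,
# physical activity, electronic media, school-related, hobbies/socialising,
# domestic/personal care/work) and a four-set subcomposition on weekend days.

N_SLOTS <- 144L

#' Behaviour-set names by day type
#'
#' @param day_type `"weekday"` (six sets) or `"weekend"` (four sets; physical
#'   activity and school are dropped because too little weekend time is spent
#'   in them to support time reallocations).
#' @return Ordered character vector of part names.
#' @export
behaviour_sets <- function(day_type = c("weekday", "weekend")) {
  day_type <- match.arg(day_type)
  if (day_type == "weekday") {
    c("sleep", "physical_activity", "media", "school", "hobbies", "domestic")
  } else {
    c("sleep", "media", "hobbies", "domestic")
  }
}

#' Construct an activity-code mapping
#'
#' @param entries Data frame with columns `activity_code` and `behaviour_set`;
#'   every code maps to exactly one of the six weekday behaviour sets.
#' @return An `activity_mapping` object.
#' @export
activity_mapping <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("activity_code", "behaviour_set")
  if (!all(need %in% names(entries))) {
    stop("mapping needs columns: ", paste(need, collapse = ", "))
  }
  entries <- entries[, need]
  entries$activity_code <- as.character(entries$activity_code)
  entries$behaviour_set <- as.character(entries$behaviour_set)
  if (anyDuplicated(entries$activity_code)) {
    stop("each activity code must map to exactly one behaviour set")
  }
  bad <- setdiff(unique(entries$behaviour_set), behaviour_sets("weekday"))
  if (length(bad)) {
    stop("unknown behaviour set(s): ", paste(bad, collapse = ", "))
  }
  structure(list(entries = entries), class = "activity_mapping")
}

#' @export
print.activity_mapping <- function(x, ...) {
  cat("Activity mapping:", nrow(x$entries), "codes ->",
      length(unique(x$entries$behaviour_set)), "behaviour sets\n")
  invisible(x)
}

#' Default activity-code mapping
#'
#' A configurable stand-in mapping from plausible diary activity codes to the
#' six behaviour sets.  Real diary instruments use their own activity
#' vocabulary; override via [read_activity_mapping()] with a project-specific
#' CSV.
#'
#' @return An `activity_mapping` object.
#' @export
default_activity_mapping <- function() {
  activity_mapping(data.frame(
    activity_code = c(
      "sleeping", "nap",
      "sports_exercise", "active_play", "walking_cycling",
      "tv_films", "video_games", "internet_browsing", "social_media",
      "school_lessons", "homework", "private_study",
      "reading_pleasure", "music_arts", "socialising", "volunteering",
      "personal_care", "eating_drinking", "household_chores", "paid_work"
    ),
    behaviour_set = c(
      "sleep", "sleep",
      "physical_activity", "physical_activity", "physical_activity",
      "media", "media", "media", "media",
      "school", "school", "school",
      "hobbies", "hobbies", "hobbies", "hobbies",
      "domestic", "domestic", "domestic", "domestic"
    ),
    stringsAsFactors = FALSE
  ))
}

#' Read an activity mapping from CSV
#'
#' @param path CSV with columns `activity_code`, `behaviour_set`.
#' @return An `activity_mapping` object.
#' @export
read_activity_mapping <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  activity_mapping(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write an activity mapping to CSV
#' @param mapping An `activity_mapping`.
#' @param path Output CSV path.
#' @export
write_activity_mapping <- function(mapping, path) {
  utils::write.csv(mapping$entries, path, row.names = FALSE)
}

map_code_to_set <- function(codes, mapping) {
  idx <- match(codes, mapping$entries$activity_code)
  out <- mapping$entries$behaviour_set[idx]
  out[is.na(codes)] <- NA_character_
  out
}

#' Construct a one-day time-use diary
#'
#' @param participant_id Identifier.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param slots Character vector of 144 activity codes; `NA` marks a slot
#'   with no activity indicated.
#' @return A `time_use_diary` object.
#' @export
time_use_diary <- function(participant_id, day_type, slots) {
  day_type <- match.arg(day_type, c("weekday", "weekend"))
  slots <- as.character(slots)
  if (length(slots) != N_SLOTS) {
    stop("a diary must contain exactly ", N_SLOTS, " slots")
  }
  structure(list(participant_id = as.character(participant_id),
                 day_type = day_type, slots = slots),
            class = "time_use_diary")
}

#' @export
print.time_use_diary <- function(x, ...) {
  cat("Time-use diary:", x$participant_id, "(", x$day_type, ");",
      sum(is.na(x$slots)), "missing slot(s)\n")
  invisible(x)
}

#' Parse a long-format diary table
#'
#' Expects columns `participant_id`, `day_type`, `slot_index` (0-143, slot 0
#' = 04:00-04:10) and `activity_code`.  Slots with no row become missing.
#' Each participant contributes at most one diary per day type; duplicate
#' (participant, day type, slot) rows are a format error.
#'
#' @param x CSV path or data frame.
#' @param mapping An `activity_mapping`; codes outside its vocabulary are a
#'   format error.
#' @return List of `time_use_diary` objects.
#' @export
parse_diary_table <- function(x, mapping) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("diary file not found: ", x)
    x <- utils::read.csv(x, stringsAsFactors = FALSE)
  }
  need <- c("participant_id", "day_type", "slot_index", "activity_code")
  if (!all(need %in% names(x))) {
    stop("diary table needs columns: ", paste(need, collapse = ", "))
  }
  x$participant_id <- as.character(x$participant_id)
  x$activity_code <- as.character(x$activity_code)
  if (!all(x$day_type %in% c("weekday", "weekend"))) {
    stop("day_type must be 'weekday' or 'weekend'")
  }
  if (any(x$slot_index < 0 | x$slot_index > (N_SLOTS - 1) |
          x$slot_index != floor(x$slot_index))) {
    stop("slot_index must be an integer in 0-", N_SLOTS - 1)
  }
  key <- paste(x$participant_id, x$day_type, x$slot_index)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate diary slot row: ", dup)
  }
  unknown <- setdiff(unique(x$activity_code), mapping$entries$activity_code)
  if (length(unknown)) {
    stop("unknown activity code(s): ", paste(unknown, collapse = ", "))
  }
  groups <- split(x, paste(x$participant_id, x$day_type, sep = "\r"),
                  drop = TRUE)
  diaries <- lapply(groups, function(g) {
    slots <- rep(NA_character_, N_SLOTS)
    slots[g$slot_index + 1L] <- g$activity_code
    time_use_diary(g$participant_id[1], g$day_type[1], slots)
  })
  names(diaries) <- NULL
  # deterministic order: by participant then day type
  ord <- order(vapply(diaries, `[[`, "", "participant_id"),
               vapply(diaries, `[[`, "", "day_type"))
  diaries[ord]
}

#' Validate a diary as a reliable account of a complete day
#'
#' A diary is invalid if any slot is missing (`missing_data`), else if it
#' records no sleep (`no_sleep`), else if it records no domestic/personal
#' care activity (`no_domestic`); that priority order is fixed.
#'
#' @param diary A `time_use_diary`.
#' @param mapping An `activity_mapping`.
#' @return List with elements `valid` (logical) and `reason` (one of
#'   `"none"`, `"missing_data"`, `"no_sleep"`, `"no_domestic"`).
#' @export
validate_diary <- function(diary, mapping) {
  stopifnot(inherits(diary, "time_use_diary"))
  sets <- map_code_to_set(diary$slots, mapping)
  if (anyNA(diary$slots)) {
    list(valid = FALSE, reason = "missing_data")
  } else if (!any(sets == "sleep")) {
    list(valid = FALSE, reason = "no_sleep")
  } else if (!any(sets == "domestic")) {
    list(valid = FALSE, reason = "no_domestic")
  } else {
    list(valid = TRUE, reason = "none")
  }
}

#' Recode a complete diary into a behaviour composition
#'
#' Minutes per behaviour set are 10 times the slot count; the six weekday
#' parts always sum to 1440.  Weekend diaries are recoded over the same six
#' sets; the four-part weekend subcomposition is taken downstream (see
#' [build_analytic_sample()]).
#'
#' @param diary A `time_use_diary` with no missing slots.
#' @param mapping An `activity_mapping`.
#' @return Named numeric vector of minutes over the six weekday sets.
#' @export
recode_diary <- function(diary, mapping) {
  stopifnot(inherits(diary, "time_use_diary"))
  if (anyNA(diary$slots)) {
    stop("diary has missing slots; validate before recoding")
  }
  sets <- map_code_to_set(diary$slots, mapping)
  if (anyNA(sets)) {
    stop("unknown activity code(s): ",
         paste(unique(diary$slots[is.na(sets)]), collapse = ", "))
  }
  parts <- behaviour_sets("weekday")
  counts <- table(factor(sets, levels = parts))
  10 * stats::setNames(as.numeric(counts), parts)
}

#' Assemble a complete-case analytic sample
#'
#' Keeps participants who have complete covariates, a valid diary of the
#' requested day type, and a non-missing outcome -- filtering in that order
#' and logging the count removed at each step.  Diaries are recoded into
#' behaviour compositions; on weekend days the four-part subcomposition
#' (dropping physical activity and school) is re-closed to 1440 minutes.
#' Zeros are retained; apply [replace_zeros()] before model fitting.
#'
#' @param diaries List of `time_use_diary` objects (all day types allowed;
#'   only the requested day type is used).
#' @param covariates Data frame with `participant_id` plus covariate columns.
#' @param outcomes Data frame with `participant_id` plus outcome column(s).
#' @param mapping An `activity_mapping`.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param outcome_name Outcome column in `outcomes`; default `"attainment8"`.
#' @param covariate_names Covariate columns required complete; default the
#'   standard adjustment set (sex, ethnicity, free school meals, maternal
#'   education).
#' @return An `analytic_sample`: list with `data` (one row per participant:
#'   parts, covariates, outcome), `removal_log`, `parts`, `day_type`,
#'   `outcome_name`.
#' @export
build_analytic_sample <- function(diaries, covariates, outcomes, mapping,
                                  day_type = c("weekday", "weekend"),
                                  outcome_name = "attainment8",
                                  covariate_names = c("sex", "ethnicity",
                                                      "fsm",
                                                      "maternal_education")) {
  day_type <- match.arg(day_type)
  stopifnot(is.data.frame(covariates), is.data.frame(outcomes))
  if (!"participant_id" %in% names(covariates) ||
      !"participant_id" %in% names(outcomes)) {
    stop("covariates and outcomes need a participant_id column")
  }
  missing_cov <- setdiff(covariate_names, names(covariates))
  if (length(missing_cov)) {
    stop("covariate column(s) not found: ", paste(missing_cov, collapse = ", "))
  }
  if (!outcome_name %in% names(outcomes)) {
    stop("outcome column not found: ", outcome_name)
  }
  covariates$participant_id <- as.character(covariates$participant_id)
  outcomes$participant_id <- as.character(outcomes$participant_id)

  dd <- Filter(function(d) d$day_type == day_type, diaries)
  ids <- vapply(dd, `[[`, "", "participant_id")
  if (anyDuplicated(ids)) {
    stop("participant(s) with more than one ", day_type, " diary: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  n0 <- length(dd)

  # step 1: complete covariates
  cov_ok <- covariates[stats::complete.cases(covariates[covariate_names]), ,
                       drop = FALSE]
  keep1 <- ids %in% cov_ok$participant_id
  n1 <- sum(keep1)

  # step 2: diary validity
  valid <- vapply(dd, function(d) validate_diary(d, mapping)$valid, NA)
  keep2 <- keep1 & valid
  n2 <- sum(keep2)

  # step 3: non-missing outcome
  out_ok <- outcomes$participant_id[!is.na(outcomes[[outcome_name]])]
  keep3 <- keep2 & (ids %in% out_ok)
  n3 <- sum(keep3)

  removal_log <- data.frame(
    step = c("covariates", "diary", "outcome"),
    removed = c(n0 - n1, n1 - n2, n2 - n3),
    remaining = c(n1, n2, n3),
    stringsAsFactors = FALSE
  )
  if (n3 == 0) stop("no participants remain after filtering")

  kept <- dd[keep3]
  comp6 <- t(vapply(kept, recode_diary, numeric(6), mapping = mapping))
  parts <- behaviour_sets(day_type)
  comp <- if (day_type == "weekend") {
    subcomposition(comp6, keep = parts)
  } else {
    comp6
  }
  kept_ids <- vapply(kept, `[[`, "", "participant_id")
  df <- data.frame(participant_id = kept_ids, comp,
                   stringsAsFactors = FALSE, row.names = NULL)
  df <- merge(df, covariates[, c("participant_id", covariate_names)],
              by = "participant_id", sort = FALSE)
  df <- merge(df, outcomes[, c("participant_id", outcome_name)],
              by = "participant_id", sort = FALSE)
  df <- df[order(df$participant_id), , drop = FALSE]
  row.names(df) <- NULL

  structure(list(data = df, removal_log = removal_log, parts = parts,
                 day_type = day_type, outcome_name = outcome_name,
                 covariate_names = covariate_names),
            class = "analytic_sample")
}

#' @export
print.analytic_sample <- function(x, ...) {
  cat("Analytic sample (", x$day_type, "): ", nrow(x$data),
      " participants, outcome '", x$outcome_name, "'\n", sep = "")
  print(x$removal_log)
  invisible(x)
}

#' Composition matrix of an analytic sample
#' @param sample An `analytic_sample`.
#' @return Numeric matrix, one composition per row (minutes).
#' @export
sample_compositions <- function(sample) {
  stopifnot(inherits(sample, "analytic_sample"))
  as.matrix(sample$data[, sample$parts, drop = FALSE])
}
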