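# Item banks and canonical delimited-text I/O for choice and cohort data.

#' The 27-item monetary choice questionnaire
#'
#' Returns the standard published item bank of the Kirby monetary choice
#' questionnaire: 27 fixed choices between a smaller immediate reward and a
#' larger delayed reward, nine items in each of three delayed-reward
#' magnitude bins (small 25--35, medium 50--60, large 75--85). Amounts are
#' unitless currency.
#'
#' @return A `data.frame` with columns `item_id`, `r_immediate`,
#'   `R_delayed`, `delay_days`, `magnitude_bin`.
#' @examples
#' bank <- mcq_item_bank()
#' table(bank$magnitude_bin)
#' @export
mcq_item_bank <- function() {
  bank <- data.frame(
    item_id = 1:27,
    r_immediate = c(54, 55, 19, 31, 14, 47, 15, 25, 78,
                    40, 11, 67, 34, 27, 69, 49, 80, 24,
                    33, 28, 34, 25, 41, 54, 54, 22, 20),
    R_delayed   = c(55, 75, 25, 85, 25, 50, 35, 60, 80,
                    55, 30, 75, 35, 50, 85, 60, 85, 35,
                    80, 30, 50, 30, 75, 60, 80, 25, 55),
    delay_days  = c(117, 61, 53, 7, 19, 160, 13, 14, 162,
                    62, 7, 119, 186, 21, 91, 89, 157, 29,
                    14, 179, 30, 80, 20, 111, 30, 136, 7),
    stringsAsFactors = FALSE
  )
  bank$magnitude_bin <- cut(bank$R_delayed, c(0, 49, 74, Inf),
                            labels = c("small", "medium", "large"))
  bank$magnitude_bin <- as.character(bank$magnitude_bin)
  bank
}

#' Discount rate at which an item is choice-indifferent
#'
#' For a choice between an immediate reward `r` and a delayed reward `R`
#' after `d` days, the hyperbolic discount rate at which both options have
#' equal subjective value is `K* = (R - r) / (r * d)`. A deterministic
#' hyperbolic discounter with rate `K` prefers the immediate reward exactly
#' when `K > K*`.
#'
#' @param item A `data.frame` (one row per item) with columns
#'   `r_immediate`, `R_delayed`, `delay_days`.
#' @return Numeric vector of indifference discount rates (1/day).
#' @examples
#' implied_item_k(data.frame(r_immediate = 66, R_delayed = 75, delay_days = 20))
#' @export
implied_item_k <- function(item) {
  stopifnot(is.data.frame(item))
  for (col in c("r_immediate", "R_delayed", "delay_days")) {
    if (!col %in% names(item)) {
      stop("implied_item_k(): missing column '", col, "'", call. = FALSE)
    }
  }
  validate_item_geometry(item$r_immediate, item$R_delayed, item$delay_days)
  (item$R_delayed - item$r_immediate) / (item$r_immediate * item$delay_days)
}

# Shared geometry checks, error names the offending field.
validate_item_geometry <- function(r_immediate, R_delayed, delay_days,
                                   rows = NULL) {
  where <- function(bad) {
    if (is.null(rows)) "" else paste0(" (row ", paste(rows[bad][1]), ")")
  }
  bad <- !is.finite(r_immediate) | r_immediate <= 0
  if (any(bad)) stop("invalid r_immediate: must be > 0", where(bad), call. = FALSE)
  bad <- !is.finite(R_delayed) | R_delayed <= r_immediate
  if (any(bad)) stop("invalid R_delayed: must exceed r_immediate", where(bad), call. = FALSE)
  bad <- !is.finite(delay_days) | delay_days < 1
  if (any(bad)) stop("invalid delay_days: must be >= 1", where(bad), call. = FALSE)
  invisible(TRUE)
}

choice_cols <- c("participant_id", "timepoint", "task_tag", "trial_index",
                 "r_immediate", "R_delayed", "delay_days", "choice")
cohort_cols <- c("participant_id", "site", "group", "arm", "relapsed",
                 "days_to_event", "dropped_out", "hamd_ma1", "hamd_ma2")

#' Read choice trials from the canonical CSV schema
#'
#' Expects a comma-separated UTF-8 file with header
#' `participant_id,timepoint,task_tag,trial_index,r_immediate,R_delayed,delay_days,choice`.
#' Unknown columns are preserved; row order is preserved. Validation errors
#' name the offending row and column.
#'
#' @param path Path to a choices CSV file.
#' @return A `data.frame` of choice trials.
#' @seealso [write_choices()]
#' @export
load_choices <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  missing <- setdiff(choice_cols, names(x))
  if (length(missing) > 0) {
    stop("choices file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) return(x)
  for (col in c("r_immediate", "R_delayed", "delay_days")) {
    x[[col]] <- parse_numeric_col(x[[col]], col)
  }
  x$trial_index <- as.integer(parse_numeric_col(x$trial_index, "trial_index"))
  validate_choices(x)
  x
}

parse_numeric_col <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & v != "" & is.na(out))
  if (length(bad) > 0) {
    stop("column '", name, "', row ", bad[1], ": unparseable value '",
         v[bad[1]], "'", call. = FALSE)
  }
  out
}

#' Validate a choice-trial data frame
#'
#' @param x A `data.frame` in the canonical choices schema.
#' @return `x` invisibly; stops with a row-numbered message on the first
#'   violation found.
#' @export
validate_choices <- function(x) {
  check_level <- function(col, levels) {
    bad <- which(is.na(x[[col]]) | !(x[[col]] %in% levels))
    if (length(bad) > 0) {
      stop("column '", col, "', row ", bad[1], ": value '",
           x[[col]][bad[1]], "' not one of {", paste(levels, collapse = ", "),
           "}", call. = FALSE)
    }
  }
  check_level("timepoint", c("MA1", "MA2"))
  check_level("task_tag", c("mcq", "adaptive"))
  check_level("choice", c("immediate", "delayed"))
  for (col in c("trial_index", "r_immediate", "R_delayed", "delay_days")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop("column '", col, "', row ", bad[1], ": unparseable value '",
           x[[col]][bad[1]], "'", call. = FALSE)
    }
  }
  if (any(x$trial_index < 1)) {
    stop("column 'trial_index': values must be >= 1", call. = FALSE)
  }
  validate_item_geometry(x$r_immediate, x$R_delayed, x$delay_days,
                         rows = seq_len(nrow(x)))
  key <- paste(x$participant_id, x$timepoint, x$task_tag, x$trial_index)
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (participant, timepoint, task, trial_index) at row ",
         dup[1], ": ", key[dup[1]], call. = FALSE)
  }
  invisible(x)
}

#' Write choice trials to the canonical CSV schema
#'
#' @param x A validated choices `data.frame`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_choices <- function(x, path) {
  stopifnot(all(choice_cols %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read participant metadata from the canonical cohort CSV schema
#'
#' One row per participant with clinical metadata: site, group
#' (patient/control), discontinuation arm, relapse status and time,
#' dropout flag, per-timepoint HAM-D scores, and any number of additional
#' rating-scale columns (preserved as-is). Empty fields are missing values.
#'
#' @param path Path to a cohort CSV file.
#' @return A `data.frame` of participant records.
#' @export
load_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  missing <- setdiff(cohort_cols, names(x))
  if (length(missing) > 0) {
    stop("cohort file missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) return(x)
  x$relapsed <- parse_logical_col(x$relapsed, "relapsed")
  x$dropped_out <- parse_logical_col(x$dropped_out, "dropped_out")
  for (col in c("days_to_event", "hamd_ma1", "hamd_ma2")) {
    x[[col]] <- parse_numeric_col(x[[col]], col)
  }
  validate_cohort(x)
  x
}

parse_logical_col <- function(v, name) {
  if (is.logical(v)) return(v)
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "true", "1")] <- TRUE
  out[v %in% c("FALSE", "false", "0")] <- FALSE
  bad <- which(!is.na(v) & v != "" & is.na(out))
  if (length(bad) > 0) {
    stop("column '", name, "', row ", bad[1], ": unparseable value '",
         v[bad[1]], "'", call. = FALSE)
  }
  out
}

#' Validate a cohort data frame
#'
#' Checks categorical levels, uniqueness of participant ids, and the
#' control-arm contract (controls have `arm = "none"` and missing relapse
#' fields).
#'
#' @param x A `data.frame` in the canonical cohort schema.
#' @return `x` invisibly.
#' @export
validate_cohort <- function(x) {
  dup <- which(duplicated(x$participant_id))
  if (length(dup) > 0) {
    stop("duplicate participant_id at row ", dup[1], ": ",
         x$participant_id[dup[1]], call. = FALSE)
  }
  bad <- which(!(x$group %in% c("patient", "control")))
  if (length(bad) > 0) {
    stop("column 'group', row ", bad[1], ": value '", x$group[bad[1]],
         "' not one of {patient, control}", call. = FALSE)
  }
  bad <- which(!(x$arm %in% c("MA1-D-MA2", "MA1-MA2-D", "none")))
  if (length(bad) > 0) {
    stop("column 'arm', row ", bad[1], ": value '", x$arm[bad[1]],
         "' not one of {MA1-D-MA2, MA1-MA2-D, none}", call. = FALSE)
  }
  ctrl <- x$group == "control"
  bad <- which(ctrl & x$arm != "none")
  if (length(bad) > 0) {
    stop("row ", bad[1], ": control participant must have arm = 'none'",
         call. = FALSE)
  }
  bad <- which(ctrl & !is.na(x$relapsed))
  if (length(bad) > 0) {
    stop("row ", bad[1], ": control participant must have missing relapse fields",
         call. = FALSE)
  }
  bad <- which(!is.na(x$days_to_event) & x$days_to_event < 0)
  if (length(bad) > 0) {
    stop("column 'days_to_event', row ", bad[1], ": negative time", call. = FALSE)
  }
  invisible(x)
}

#' Write participant metadata to the canonical cohort CSV schema
#'
#' @param x A cohort `data.frame`.
#' @param path Output file path.
#' @return `path` invisibly.
#' @export
write_cohort <- function(x, path) {
  stopifnot(all(cohort_cols %in% names(x)))
  utils::write.csv(x, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
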