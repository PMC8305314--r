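#' Read an mAAT session from disk
#'
#' Two on-disk formats are supported. The canonical format is JSON, one file
#' per session, with nested per-trial traces (traces are ragged, so JSON nests
#' them naturally). A long-format CSV is accepted for interoperability: one
#' row per sensor sample plus `rating` and `session` record rows, discriminated
#' by a `record_type` column. Both formats round-trip through
#' [write_session()] without loss.
#'
#' Trials whose trace has non-monotone timestamps are rejected with a warning;
#' the rejection reasons are kept in the `parse_warnings` attribute of the
#' returned session. A missing mandatory field raises a schema error naming
#' the trial index and field.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"json"` or `"csv"`.
#' @return A [maat_session()].
#' @export
read_session <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("no such session file: ", path), class = "maatkit_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") read_session_json(path) else read_session_csv(path)
}

#' Write an mAAT session to disk
#'
#' @param session A [maat_session()].
#' @inheritParams read_session
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(session, "maat_session"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "json") write_session_json(session, path)
  else write_session_csv(session, path)
  invisible(path)
}

# --- JSON ------------------------------------------------------------------

schema_abort <- function(trial, field) {
  abort(sprintf("trial %d: mandatory field '%s' missing or null", trial, field),
        class = "maatkit_schema_error")
}

read_session_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (f in c("participant_id", "trials")) {
    if (is.null(raw[[f]])) {
      abort(paste0("session is missing mandatory field '", f, "'"),
            class = "maatkit_schema_error")
    }
  }
  warnings <- character()
  rows <- list()
  for (i in seq_along(raw$trials)) {
    tr <- raw$trials[[i]]
    for (f in c("block", "stimulus_id", "category", "instructed_direction",
                "stim_onset", "trace")) {
      if (is.null(tr[[f]])) schema_abort(i, f)
    }
    for (f in c("t", "acc")) {
      if (is.null(tr$trace[[f]])) schema_abort(i, paste0("trace.", f))
    }
    t <- as.numeric(unlist(tr$trace$t))
    acc <- do.call(rbind, lapply(tr$trace$acc, as.numeric))
    if (is.null(acc) || ncol(acc) != 3L || nrow(acc) != length(t)) {
      schema_abort(i, "trace.acc")
    }
    trace <- tibble::tibble(t = t, ax = acc[, 1], ay = acc[, 2], az = acc[, 3])
    if (!is.null(tr$trace$gyro) && length(tr$trace$gyro) > 0L) {
      gyro <- do.call(rbind, lapply(tr$trace$gyro, as.numeric))
      if (!is.null(gyro) && nrow(gyro) == length(t) && ncol(gyro) == 3L) {
        trace$gx <- gyro[, 1]; trace$gy <- gyro[, 2]; trace$gz <- gyro[, 3]
      }
    }
    if (any(diff(t) <= 0)) {
      msg <- sprintf("trial %d: non-monotone timestamps; trace rejected", i)
      warnings <- c(warnings, msg)
      warn(msg)
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      block = as.integer(tr$block),
      stimulus_id = as.character(tr$stimulus_id),
      category = as.character(tr$category),
      instructed_direction = as.character(tr$instructed_direction),
      stim_onset = as.numeric(tr$stim_onset),
      has_linear_accelerometer =
        isTRUE(tr$trace$has_linear_accelerometer),
      trace = list(trace)
    )
  }
  if (length(rows) == 0L) {
    abort("session contains no readable trials", class = "maatkit_schema_error")
  }
  ratings <- NULL
  if (!is.null(raw$ratings) && length(raw$ratings) > 0L) {
    ratings <- dplyr::bind_rows(lapply(raw$ratings, function(r) {
      tibble::tibble(stimulus_id = as.character(r$stimulus_id),
                     category = as.character(r$category),
                     valence = as.numeric(r$valence),
                     arousal = as.numeric(r$arousal),
                     wanting = as.numeric(r$wanting))
    }))
  }
  s <- maat_session(
    participant_id = as.character(raw$participant_id),
    trials = dplyr::bind_rows(rows),
    ratings = ratings,
    neophobia_score = if (is.null(raw$neophobia_score)) NA_real_
                      else as.numeric(raw$neophobia_score),
    axis_convention = raw$axis_convention %||% "+z_toward_face"
  )
  attr(s, "parse_warnings") <- warnings
  s
}

write_session_json <- function(session, path) {
  trials <- lapply(seq_len(nrow(session$trials)), function(i) {
    row <- session$trials[i, ]
    tr <- row$trace[[1L]]
    has_gyro <- all(c("gx", "gy", "gz") %in% names(tr))
    list(
      block = row$block,
      stimulus_id = row$stimulus_id,
      category = row$category,
      instructed_direction = row$instructed_direction,
      stim_onset = row$stim_onset,
      trace = list(
        t = tr$t,
        acc = unname(as.matrix(tr[, c("ax", "ay", "az")])),
        gyro = if (has_gyro) unname(as.matrix(tr[, c("gx", "gy", "gz")])) else NULL,
        has_linear_accelerometer = row$has_linear_accelerometer
      )
    )
  })
  obj <- list(
    participant_id = session$participant_id,
    axis_convention = session$axis_convention,
    trials = trials,
    ratings = session$ratings,
    neophobia_score = if (is.na(session$neophobia_score)) NULL
                      else session$neophobia_score
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
}

# --- CSV (long format) -----------------------------------------------------

csv_cols <- c("record_type", "participant_id", "axis_convention", "trial",
              "block", "stimulus_id", "category", "instructed_direction",
              "stim_onset", "has_linear_accelerometer", "t", "ax", "ay", "az",
              "gx", "gy", "gz", "valence", "arousal", "wanting",
              "neophobia_score")

write_session_csv <- function(session, path) {
  samples <- purrr::map_dfr(seq_len(nrow(session$trials)), function(i) {
    row <- session$trials[i, ]
    tr <- row$trace[[1L]]
    out <- tibble::tibble(
      record_type = "trial_sample",
      participant_id = session$participant_id,
      axis_convention = session$axis_convention,
      trial = i,
      block = row$block,
      stimulus_id = row$stimulus_id,
      category = row$category,
      instructed_direction = row$instructed_direction,
      stim_onset = row$stim_onset,
      has_linear_accelerometer = row$has_linear_accelerometer,
      t = tr$t, ax = tr$ax, ay = tr$ay, az = tr$az
    )
    if (all(c("gx", "gy", "gz") %in% names(tr))) {
      out$gx <- tr$gx; out$gy <- tr$gy; out$gz <- tr$gz
    } else {
      out$gx <- NA_real_; out$gy <- NA_real_; out$gz <- NA_real_
    }
    out
  })
  extra <- tibble::tibble(
    record_type = "session",
    participant_id = session$participant_id,
    axis_convention = session$axis_convention,
    neophobia_score = session$neophobia_score
  )
  if (!is.null(session$ratings) && nrow(session$ratings) > 0L) {
    ratings <- dplyr::mutate(session$ratings,
                             record_type = "rating",
                             participant_id = session$participant_id,
                             axis_convention = session$axis_convention)
    extra <- dplyr::bind_rows(extra, ratings)
  }
  full <- dplyr::bind_rows(samples, extra)
  for (col in setdiff(csv_cols, names(full))) full[[col]] <- NA
  readr::write_csv(full[, csv_cols], path, na = "")
}

read_session_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = "",
                        col_types = readr::cols(
                          record_type = "c", participant_id = "c",
                          axis_convention = "c", trial = "i", block = "i",
                          stimulus_id = "c", category = "c",
                          instructed_direction = "c",
                          has_linear_accelerometer = "l",
                          .default = "d"))
  if (!"record_type" %in% names(df)) {
    abort("CSV session file lacks a 'record_type' column",
          class = "maatkit_schema_error")
  }
  samples <- dplyr::filter(df, .data$record_type == "trial_sample")
  if (nrow(samples) == 0L) {
    abort("CSV session file contains no trial_sample rows",
          class = "maatkit_schema_error")
  }
  for (f in c("participant_id", "trial", "block", "stimulus_id", "category",
              "instructed_direction", "stim_onset", "t", "ax", "ay", "az")) {
    if (anyNA(samples[[f]])) {
      bad <- which(is.na(samples[[f]]))[1L]
      abort(sprintf("CSV row %d: mandatory field '%s' missing", bad, f),
            class = "maatkit_schema_error")
    }
  }
  has_gyro <- !all(is.na(samples$gx))
  warnings <- character()
  trials <- samples |>
    dplyr::group_split(.data$trial) |>
    purrr::map_dfr(function(g) {
      trace <- tibble::tibble(t = g$t, ax = g$ax, ay = g$ay, az = g$az)
      if (has_gyro) { trace$gx <- g$gx; trace$gy <- g$gy; trace$gz <- g$gz }
      tibble::tibble(
        block = g$block[1L],
        stimulus_id = g$stimulus_id[1L],
        category = g$category[1L],
        instructed_direction = g$instructed_direction[1L],
        stim_onset = g$stim_onset[1L],
        has_linear_accelerometer = isTRUE(g$has_linear_accelerometer[1L]),
        trace = list(trace)
      )
    })
  keep <- vapply(trials$trace, function(tr) all(diff(tr$t) > 0), logical(1))
  if (any(!keep)) {
    for (i in which(!keep)) {
      msg <- sprintf("trial %d: non-monotone timestamps; trace rejected", i)
      warnings <- c(warnings, msg)
      warn(msg)
    }
    trials <- trials[keep, ]
  }
  ratings_rows <- dplyr::filter(df, .data$record_type == "rating")
  ratings <- NULL
  if (nrow(ratings_rows) > 0L) {
    ratings <- dplyr::select(ratings_rows, "stimulus_id", "category",
                             "valence", "arousal", "wanting")
  }
  session_row <- dplyr::filter(df, .data$record_type == "session")
  neo <- if (nrow(session_row) > 0L) session_row$neophobia_score[1L] else NA_real_
  s <- maat_session(
    participant_id = samples$participant_id[1L],
    trials = trials,
    ratings = ratings,
    neophobia_score = neo,
    axis_convention = samples$axis_convention[1L] %||% "+z_toward_face"
  )
  attr(s, "parse_warnings") <- warnings
  s
}

# --- metrics table ---------------------------------------------------------

metrics_cols <- c("participant_id", "block", "stimulus_id", "category",
                  "instructed_direction", "rt_ms", "distance_m",
                  "peak_acc_ms2", "observed_direction", "status")

#' Write a per-trial metrics table to CSV
#'
#' One row per trial with the fixed column set `participant_id`, `block`,
#' `stimulus_id`, `category`, `instructed_direction`, `rt_ms`, `distance_m`,
#' `peak_acc_ms2`, `observed_direction`, `status`. Status is serialized as a
#' lowercase token from `valid`, `too_fast`, `no_reaction`, `no_onset`.
#' Re-reading with [read_metrics_table()] reproduces enum and integer columns
#' bit-identically and reals to better than 1e-9.
#'
#' @param metrics Metrics tibble from [process_session()] / [apply_qc()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  stopifnot(nrow(metrics) > 0L)
  missing <- setdiff(metrics_cols, names(metrics))
  if (length(missing) > 0L) {
    abort(paste0("metrics table missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "maatkit_schema_error")
  }
  readr::write_csv(metrics[, metrics_cols], path, na = "")
  invisible(path)
}

#' Read a per-trial metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return A tibble with the fixed metrics column set.
#' @export
read_metrics_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, na = "",
                  col_types = readr::cols(
                    participant_id = "c", block = "i", stimulus_id = "c",
                    category = "c", instructed_direction = "c",
                    rt_ms = "d", distance_m = "d", peak_acc_ms2 = "d",
                    observed_direction = "c", status = "c"))
}
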