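#' Construct an mAAT session
#'
#' A session bundles everything one participant produced: the ordered trials
#' with their raw sensor traces, optional explicit image ratings, and an
#' optional food-neophobia questionnaire score.
#'
#' @param participant_id Opaque participant identifier (single string).
#' @param trials Tibble with one row per trial and columns `block` (integer),
#'   `stimulus_id` (character), `category` (one of `"palatable"`,
#'   `"unpalatable"`, `"dutch"`, `"asian"`), `instructed_direction` (`"pull"`
#'   or `"push"`), `stim_onset` (seconds on the trace clock),
#'   `has_linear_accelerometer` (logical; `TRUE` means the device already
#'   removed gravity) and `trace` (list-column of trace tibbles, see Details).
#' @param ratings Optional tibble with columns `stimulus_id`, `category`,
#'   `valence`, `arousal`, `wanting`, each rating bounded in \[0, 100\].
#' @param neophobia_score Optional food-neophobia sum score (10-70 for the
#'   10-item 7-point scale), `NA` when not collected.
#' @param axis_convention Device axis convention. Only `"+z_toward_face"` is
#'   defined: the positive z axis points out of the screen toward the
#'   participant's face, so a pull movement has positive z displacement.
#'
#' @details
#' A trace tibble has columns `t` (seconds since trial start, strictly
#' increasing), `ax`, `ay`, `az` (acceleration in m/s^2, device frame) and
#' optionally `gx`, `gy`, `gz` (rotational rate in rad/s). Gyroscope columns
#' are carried through but unused by the default pipeline.
#'
#' @return An object of class `maat_session`.
#' @seealso [read_session()], [validate_session()], [process_session()]
#' @export
#' @examples
#' sim <- simulate_trace(trace_sim_config(seed = 1))
#' trials <- tibble::tibble(
#'   block = 1L, stimulus_id = "img01", category = "palatable",
#'   instructed_direction = "pull", stim_onset = 0.5,
#'   has_linear_accelerometer = FALSE, trace = list(sim$trace)
#' )
#' maat_session("p01", trials)
maat_session <- function(participant_id, trials, ratings = NULL,
                         neophobia_score = NA_real_,
                         axis_convention = "+z_toward_face") {
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  trials <- tibble::as_tibble(trials)
  needed <- c("block", "stimulus_id", "category", "instructed_direction",
              "stim_onset", "has_linear_accelerometer", "trace")
  missing <- setdiff(needed, names(trials))
  if (length(missing) > 0L) {
    abort(paste0("trials is missing column(s): ", paste(missing, collapse = ", ")),
          class = "maatkit_schema_error")
  }
  if (nrow(trials) == 0L) {
    abort("a session must contain at least one trial",
          class = "maatkit_schema_error")
  }
  if (!is.null(ratings)) ratings <- tibble::as_tibble(ratings)
  structure(
    list(participant_id = participant_id,
         axis_convention = axis_convention,
         trials = trials,
         ratings = ratings,
         neophobia_score = as.numeric(neophobia_score)),
    class = "maat_session"
  )
}

#' @export
print.maat_session <- function(x, ...) {
  cat("<maat_session> participant", x$participant_id, "\n")
  cat("  trials:", nrow(x$trials), "\n")
  cat("  ratings:", if (is.null(x$ratings)) "none" else nrow(x$ratings), "\n")
  cat("  neophobia score:",
      if (is.na(x$neophobia_score)) "none" else x$neophobia_score, "\n")
  invisible(x)
}

#' Validate an mAAT session against its structural invariants
#'
#' Checks every invariant the processing pipeline relies on and reports all
#' violations rather than stopping at the first. An empty report means the
#' session is processable.
#'
#' Checked per trace: strictly increasing timestamps, finite samples, a median
#' sampling interval between 1 and 100 ms, and a stimulus onset inside the
#' trace span. Checked per session: category/direction enumerations, rating
#' bounds in \[0, 100\], and neophobia score in \[10, 70\] when present.
#'
#' @param session A [maat_session()].
#' @return A tibble with columns `trial` (row index into the trials table,
#'   `NA` for session-level problems), `field` and `message`; zero rows when
#'   the session is clean.
#' @export
validate_session <- function(session) {
  stopifnot(inherits(session, "maat_session"))
  out <- list()
  bad <- function(trial, field, message) {
    tibble::tibble(trial = as.integer(trial), field = field, message = message)
  }

  trials <- session$trials
  for (i in seq_len(nrow(trials))) {
    tr <- trials$trace[[i]]
    if (!trials$category[i] %in% categories) {
      out[[length(out) + 1L]] <- bad(i, "category",
        paste0("category '", trials$category[i], "' not one of: ",
               paste(categories, collapse = ", ")))
    }
    if (!trials$instructed_direction[i] %in% directions) {
      out[[length(out) + 1L]] <- bad(i, "instructed_direction",
        paste0("direction '", trials$instructed_direction[i],
               "' not 'pull' or 'push'"))
    }
    if (is.null(tr) || nrow(tr) < 2L) {
      out[[length(out) + 1L]] <- bad(i, "trace", "trace absent or < 2 samples")
      next
    }
    if (anyNA(tr) || !all(is.finite(as.matrix(tr)))) {
      out[[length(out) + 1L]] <- bad(i, "trace", "non-finite samples in trace")
    }
    dt <- diff(tr$t)
    if (any(dt <= 0)) {
      out[[length(out) + 1L]] <- bad(i, "trace",
        "timestamps not strictly increasing (duplicate or reversed)")
    } else {
      mdt <- median(dt)
      if (mdt <= 0.001 || mdt >= 0.1) {
        out[[length(out) + 1L]] <- bad(i, "trace",
          sprintf("median sampling interval %.4f s outside (0.001, 0.1)", mdt))
      }
    }
    so <- trials$stim_onset[i]
    if (!is.finite(so) || so < tr$t[1L] || so > tr$t[nrow(tr)]) {
      out[[length(out) + 1L]] <- bad(i, "stim_onset",
        sprintf("stim_onset %.3f outside trace span [%.3f, %.3f]",
                so, tr$t[1L], tr$t[nrow(tr)]))
    }
  }

  if (!is.null(session$ratings) && nrow(session$ratings) > 0L) {
    r <- session$ratings
    for (col in c("valence", "arousal", "wanting")) {
      if (!col %in% names(r)) {
        out[[length(out) + 1L]] <- bad(NA, col, "rating column missing")
      } else if (any(r[[col]] < 0 | r[[col]] > 100, na.rm = TRUE)) {
        out[[length(out) + 1L]] <- bad(NA, col, "rating outside [0, 100]")
      }
    }
  }
  if (!is.na(session$neophobia_score) &&
      (session$neophobia_score < 10 || session$neophobia_score > 70)) {
    out[[length(out) + 1L]] <- bad(NA, "neophobia_score",
                                   "neophobia score outside [10, 70]")
  }

  if (length(out) == 0L) {
    tibble::tibble(trial = integer(), field = character(), message = character())
  } else {
    dplyr::bind_rows(out)
  }
}
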