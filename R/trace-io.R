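# Readers/writers for every artifact format: trace tables, condition
# manifests, ground truth, per-molecule records and result objects.

#' Read a per-condition trace table
#'
#' The trace-table dialect is a delimited file (comma or tab, sniffed from
#' the header) with mandatory header `molecule_id, frame_index, donor,
#' acceptor`; `frame_index` is 0-based and must be gapless within each
#' molecule. Frame times are `frame_index * frame_interval` (frame start).
#'
#' @param path File path.
#' @param frame_interval Seconds per frame (> 0).
#' @return Tibble `molecule_id`, `frame`, `donor`, `acceptor`, sorted by
#'   molecule and frame, with a `frame_interval` attribute.
#' @export
read_traces <- function(path, frame_interval) {
  check_number(frame_interval, "frame_interval", min = .Machine$double.eps)
  if (!file.exists(path)) {
    abort(sprintf("trace file not found: %s", path))
  }
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header)) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  required <- c("molecule_id", "frame_index", "donor", "acceptor")
  missing <- setdiff(required, names(dat))
  if (length(missing)) {
    abort(sprintf("trace table %s is missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  for (col in c("frame_index", "donor", "acceptor")) {
    if (!is.numeric(dat[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(dat[[col]]))))[1L]
      abort(sprintf("non-numeric value in column `%s` at data row %d of %s",
                    col, bad, path))
    }
  }
  dat <- dat |>
    dplyr::transmute(
      molecule_id = as.character(.data$molecule_id),
      frame = as.integer(.data$frame_index),
      donor = as.numeric(.data$donor),
      acceptor = as.numeric(.data$acceptor)
    ) |>
    dplyr::arrange(.data$molecule_id, .data$frame)

  dup <- dat |>
    dplyr::count(.data$molecule_id, .data$frame) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    abort(sprintf("duplicate (molecule_id, frame_index) in %s: %s frame %d",
                  path, dup$molecule_id[1L], dup$frame[1L]))
  }
  gaps <- dat |>
    dplyr::summarise(
      first = .data$frame[1L],
      gap_at = {
        d <- diff(.data$frame)
        if (any(d != 1L)) .data$frame[which(d != 1L)[1L]] else NA_integer_
      },
      .by = "molecule_id"
    ) |>
    dplyr::filter(.data$first != 0L | !is.na(.data$gap_at))
  if (nrow(gaps)) {
    g <- gaps[1L, ]
    where <- if (g$first != 0L) g$first else g$gap_at
    abort(sprintf(
      "frame_index gap for molecule %s of %s: discontinuity at frame %d",
      g$molecule_id, path, where))
  }
  attr(dat, "frame_interval") <- frame_interval
  dat
}

#' Write a trace table
#'
#' Deterministic column order (`molecule_id`, `frame_index`, `donor`,
#' `acceptor`); intensities serialized with 6 significant digits.
#'
#' @param traces Tibble with `molecule_id`, `frame`, `donor`, `acceptor`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  out <- tibble::tibble(
    molecule_id = traces$molecule_id,
    frame_index = traces$frame,
    donor = signif(traces$donor, 6),
    acceptor = signif(traces$acceptor, 6)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a condition manifest
#'
#' A manifest (YAML or JSON, by extension) describes one condition: fields
#' `condition_name`, `role` (`"reference"` or `"ligand"`), `ligand_name`
#' (required when role is ligand), `trace_file` (resolved relative to the
#' manifest), `frame_interval` (seconds), optional `notes`. Measurements with
#' ligands are paired to the reference measured immediately before them; the
#' pairing is expressed by feeding both manifests to the same analysis run.
#'
#' @param path Manifest file path.
#' @return A `condition_manifest` list.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("manifest not found: %s", path))
  }
  m <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  for (f in c("condition_name", "role", "trace_file", "frame_interval")) {
    if (is.null(m[[f]])) {
      abort(sprintf("manifest %s is missing field `%s`", path, f))
    }
  }
  if (!m$role %in% c("reference", "ligand")) {
    abort(sprintf("manifest %s: `role` must be \"reference\" or \"ligand\"",
                  path))
  }
  if (m$role == "ligand" && is.null(m$ligand_name)) {
    abort(sprintf("manifest %s: role \"ligand\" requires `ligand_name`",
                  path))
  }
  check_number(m$frame_interval, "frame_interval",
               min = .Machine$double.eps)
  trace_file <- m$trace_file
  if (!file.exists(trace_file)) {
    trace_file <- file.path(dirname(path), m$trace_file)
  }
  if (!file.exists(trace_file)) {
    abort(sprintf("manifest %s: trace_file does not exist: %s", path,
                  m$trace_file))
  }
  structure(
    list(condition_name = m$condition_name, role = m$role,
         ligand_name = m$ligand_name %||% NA_character_,
         trace_file = trace_file,
         frame_interval = as.numeric(m$frame_interval),
         notes = m$notes %||% ""),
    class = "condition_manifest"
  )
}

#' Write ground truth to JSON
#'
#' Schema per molecule: `molecule_id`, `conformer`, `events` (seconds),
#' `bleach` (`donor`/`acceptor`, `null` when the fluorophore never bleaches
#' within the recording).
#'
#' @param truth Ground-truth tibble from [simulate_condition()].
#' @param path Output JSON path.
#' @param total_time Recording length, seconds; bleach times beyond it are
#'   written as `null`.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, total_time = Inf) {
  recs <- purrr::pmap(
    list(truth$molecule_id, truth$conformer, truth$event_times,
         truth$bleach_donor, truth$bleach_acceptor),
    function(id, conf, ev, bd, ba) {
      list(
        molecule_id = id, conformer = conf,
        events = as.numeric(signif(ev, 6)),
        bleach = list(
          donor = if (is.finite(bd) && bd < total_time) signif(bd, 6),
          acceptor = if (is.finite(ba) && ba < total_time) signif(ba, 6)
        )
      )
    }
  )
  jsonlite::write_json(recs, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

result_payload <- function(x) {
  UseMethod("result_payload")
}

#' @export
result_payload.rate_estimate <- function(x) {
  list(type = "rate_estimate", condition_name = x$condition_name,
       n_molecules = x$n_molecules, n_events = x$n_events,
       total_time = signif(x$total_time, 6),
       pooled_rate = signif(x$pooled_rate, 6),
       mean_of_rates = signif(x$mean_of_rates, 6))
}

#' @export
result_payload.rate_bootstrap <- function(x) {
  list(type = "rate_bootstrap", n_boot = x$n_boot, seed = x$seed,
       n_molecules = x$n_molecules,
       gaussian_mean = signif(x$gaussian_mean, 6),
       gaussian_sd = signif(x$gaussian_sd, 6),
       ci_low = signif(x$ci_low, 6), ci_high = signif(x$ci_high, 6),
       note = if (!is.na(x$note)) x$note)
}

#' @export
result_payload.relative_rate_result <- function(x) {
  list(type = "relative_rate_result", condition_name = x$condition_name,
       reference_name = x$reference_name,
       relative_rate = signif(x$relative_rate, 6),
       relative_percent = round(100 * x$relative_rate))
}

#' @export
result_payload.relative_activity_result <- function(x) {
  list(type = "relative_activity_result", condition_name = x$condition_name,
       reference_name = x$reference_name, t_ref = x$t_ref,
       removed_fraction_condition = signif(x$removed_fraction_condition, 6),
       removed_fraction_reference = signif(x$removed_fraction_reference, 6),
       relative_activity = signif(x$relative_activity, 6),
       replicate_sd = if (!is.na(x$replicate_sd)) signif(x$replicate_sd, 6))
}

#' Write analysis results to disk
#'
#' Result objects (`rate_estimate`, `rate_bootstrap`,
#' `relative_rate_result`, `relative_activity_result`, or a named list of
#' them) are serialized to JSON with stable key order and 6 significant
#' digits; per-molecule record tibbles go to CSV. Writers are pure: the same
#' input always produces the same bytes.
#'
#' @param results A result object, a named list of them, or a per-molecule
#'   record tibble.
#' @param path Output path (`.json` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  if (is.data.frame(results)) {
    out <- results
    if ("event_frames" %in% names(out)) {
      out$event_frames <- vapply(out$event_frames, paste, character(1),
                                 collapse = ";")
    }
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n_events"
    out[num] <- lapply(out[num], signif, digits = 6)
    readr::write_csv(out, path, progress = FALSE)
    return(invisible(path))
  }
  payload <- if (inherits(results, c("rate_estimate", "rate_bootstrap",
                                     "relative_rate_result",
                                     "relative_activity_result"))) {
    result_payload(results)
  } else {
    lapply(results, function(x) {
      if (is.data.frame(x) || is.atomic(x)) x else result_payload(x)
    })
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a spot-count CSV (`time_s`, `count`)
#'
#' @param path CSV path.
#' @param condition_name Label attached to the series.
#' @return A `spot_count_series` (see [count_series()]).
#' @export
read_counts_csv <- function(path, condition_name = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("counts file not found: %s", path))
  }
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_s", "count") %in% names(dat))) {
    abort(sprintf("counts file %s must have columns time_s, count", path))
  }
  count_series(counts = dat$count, times = dat$time_s,
               condition_name = condition_name %||%
                 sub("\\.[^.]*$", "", basename(path)))
}

#' Write a spot-count series as CSV
#'
#' @param series A `spot_count_series`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(series, path) {
  readr::write_csv(
    tibble::tibble(time_s = series$time_s, count = series$count,
                   percent_remaining = signif(series$percent_remaining, 6)),
    path, progress = FALSE)
  invisible(path)
}
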