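# Dual-cutoff contact detection and per-residue interaction metrics.
#
# A contact starts when the minimum distance drops strictly below the lower
# cutoff and survives until it reaches (>=) the upper cutoff. The hysteresis
# band suppresses "rattling in a cage": rapid excursions between the two
# cutoffs do not split a bound episode into many short contacts.

#' Dual distance cutoffs
#'
#' @param lower,upper Cutoffs in nm, `0 < lower <= upper`. With
#'   `lower == upper` the scheme degenerates to a single cutoff.
#' @return A `cutoff_pair` object.
#' @export
cutoff_pair <- function(lower, upper) {
  if (!is.numeric(lower) || !is.numeric(upper) || lower <= 0 || lower > upper) {
    stop_ls("invalid cutoffs: need 0 < lower <= upper, got (%s, %s)", lower, upper)
  }
  structure(list(lower = lower, upper = upper), class = "cutoff_pair")
}

#' Detect dual-cutoff contact events in a distance series
#'
#' Runs the hysteresis state machine over a per-frame minimum-distance
#' series: OFF -> ON when `distance < lower`, ON -> OFF when
#' `distance >= upper`. An episode still ON at the last frame is closed
#' there. A one-frame contact has duration `dt`.
#'
#' @param distances Numeric vector of per-frame minimum distances (nm), or a
#'   tibble from [min_distance_series()].
#' @param cutoffs A [cutoff_pair()].
#' @param dt Time per frame (ns).
#' @param residue,molecule_id,traj_id Identifiers copied onto the events.
#' @return Tibble of events: `residue`, `molecule_id`, `traj_id`,
#'   `start_frame`, `end_frame` (closed interval, 1-based), `duration` (ns).
#' @export
detect_events <- function(distances, cutoffs, dt,
                          residue = NA_integer_, molecule_id = NA_integer_,
                          traj_id = NA_integer_) {
  if (is.data.frame(distances)) {
    if (!is.na(distances$residue[1])) residue <- distances$residue[1]
    if (!is.na(distances$molecule_id[1])) molecule_id <- distances$molecule_id[1]
    distances <- distances$distance
  }
  if (length(distances) == 0L) stop_ls("empty distance series")
  stopifnot(inherits(cutoffs, "cutoff_pair"))

  on <- FALSE
  start <- integer()
  end <- integer()
  cur <- NA_integer_
  for (i in seq_along(distances)) {
    if (!on) {
      if (distances[i] < cutoffs$lower) {
        on <- TRUE
        cur <- i
      }
    } else if (distances[i] >= cutoffs$upper) {
      start <- c(start, cur)
      end <- c(end, i - 1L)
      on <- FALSE
      # the frame that ends one episode may immediately start another only
      # when below lower, which is impossible here since upper >= lower
    }
  }
  if (on) {
    start <- c(start, cur)
    end <- c(end, length(distances))
  }
  tibble::tibble(
    residue = rep(residue, length(start)),
    molecule_id = rep(molecule_id, length(start)),
    traj_id = rep(traj_id, length(start)),
    start_frame = start, end_frame = end,
    duration = (end - start + 1L) * dt
  )
}

#' Per-frame contact index under the lower cutoff
#'
#' For every residue and frame, which ligand copies sit strictly below the
#' lower cutoff. Occupancy and lipid count are defined on this index.
#'
#' @param model A `system_model` (or a precomputed distance matrix list).
#' @param cutoffs A [cutoff_pair()]; only `lower` is used.
#' @param n_workers Worker processes for the distance computation.
#' @return Tibble `residue`, `frame`, `molecule_id` with one row per contact
#'   (frames with no contact are absent), plus attribute `n_frames`.
#' @export
frame_contact_index <- function(model, cutoffs, n_workers = 1L) {
  dml <- if (inherits(model, "system_model")) {
    distance_matrix_list(model, n_workers = n_workers)
  } else {
    model
  }
  n_frames <- ncol(dml[[1]])
  rows <- lapply(names(dml), function(rn) {
    hit <- which(dml[[rn]] < cutoffs$lower, arr.ind = TRUE)
    if (nrow(hit) == 0L) {
      return(NULL)
    }
    tibble::tibble(
      residue = as.integer(rn), frame = as.integer(hit[, 2]),
      molecule_id = as.integer(hit[, 1])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      residue = integer(), frame = integer(), molecule_id = integer()
    )
  }
  out <- dplyr::arrange(out, .data$residue, .data$frame, .data$molecule_id)
  attr(out, "n_frames") <- n_frames
  out
}

#' Detect all contact events of one or more models
#'
#' Convenience wrapper running [detect_events()] over every
#' (residue, ligand copy, repeat) distance series. Episodes never span
#' repeats.
#'
#' @param models A `system_model` or list of them (repeats).
#' @param cutoffs A [cutoff_pair()].
#' @param n_workers Worker processes.
#' @return Tibble of events across all repeats.
#' @export
detect_all_events <- function(models, cutoffs, n_workers = 1L) {
  if (inherits(models, "system_model")) models <- list(models)
  dplyr::bind_rows(lapply(models, function(model) {
    dml <- distance_matrix_list(model, n_workers = n_workers)
    dplyr::bind_rows(lapply(names(dml), function(rn) {
      mat <- dml[[rn]]
      dplyr::bind_rows(lapply(seq_len(nrow(mat)), function(li) {
        detect_events(mat[li, ], cutoffs, model$dt,
          residue = as.integer(rn), molecule_id = li,
          traj_id = model$traj_id
        )
      }))
    }))
  }))
}

#' Per-residue interaction metrics
#'
#' Combines contact events and the frame contact index into the standard
#' per-residue summary: mean contact duration (ns), occupancy (% of frames
#' with at least one ligand in contact) and lipid count (mean number of
#' simultaneously contacting ligand copies over contact frames). Each metric
#' is computed per repeat and then averaged over repeats.
#'
#' @param events Event tibble from [detect_all_events()].
#' @param frame_index List of per-repeat tibbles from [frame_contact_index()]
#'   (or a single tibble for one repeat).
#' @param n_frames Integer vector: frames per repeat (defaults to the
#'   `n_frames` attributes of `frame_index`).
#' @param residues Residue serials to report (defaults to those seen).
#' @return Tibble `residue`, `mean_duration`, `occupancy`, `lipid_count`.
#' @export
residue_metrics <- function(events, frame_index, n_frames = NULL,
                            residues = NULL) {
  if (is.data.frame(frame_index)) frame_index <- list(frame_index)
  if (is.null(n_frames)) {
    n_frames <- vapply(frame_index, function(fi) attr(fi, "n_frames"), numeric(1))
  }
  if (any(!is.finite(n_frames)) || any(n_frames <= 0)) {
    stop_ls("metrics undefined for zero frames")
  }
  if (is.null(residues)) {
    residues <- sort(unique(c(
      events$residue,
      unlist(lapply(frame_index, function(fi) fi$residue))
    )))
  }

  per_rep <- dplyr::bind_rows(lapply(seq_along(frame_index), function(rep_i) {
    fi <- frame_index[[rep_i]]
    nf <- n_frames[rep_i]
    per_frame <- fi |>
      dplyr::count(.data$residue, .data$frame, name = "n_mol")
    occ <- per_frame |>
      dplyr::group_by(.data$residue) |>
      dplyr::summarise(
        occupancy = 100 * dplyr::n() / nf,
        lipid_count = mean(.data$n_mol),
        .groups = "drop"
      )
    occ$rep <- rep_i
    occ
  }))

  dur_rep <- events |>
    dplyr::group_by(.data$residue, .data$traj_id) |>
    dplyr::summarise(mean_duration = mean(.data$duration), .groups = "drop")

  tibble::tibble(residue = residues) |>
    dplyr::left_join(
      per_rep |>
        dplyr::group_by(.data$residue) |>
        dplyr::summarise(
          occupancy = sum(.data$occupancy) / length(frame_index),
          lipid_count = sum(.data$lipid_count) / length(frame_index),
          .groups = "drop"
        ),
      by = "residue"
    ) |>
    dplyr::left_join(
      dur_rep |>
        dplyr::group_by(.data$residue) |>
        dplyr::summarise(mean_duration = mean(.data$mean_duration), .groups = "drop"),
      by = "residue"
    ) |>
    dplyr::mutate(
      occupancy = dplyr::coalesce(.data$occupancy, 0),
      lipid_count = dplyr::coalesce(.data$lipid_count, 0),
      mean_duration = dplyr::coalesce(.data$mean_duration, 0)
    ) |>
    dplyr::select(
      "residue", "mean_duration", "occupancy", "lipid_count"
    )
}
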