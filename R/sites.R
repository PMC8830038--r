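# Binding sites: communities of the residue network, size-filtered, with
# site-level contact events, kinetics and surface areas.

#' Filter communities into binding-site skeletons
#'
#' Communities smaller than `min_size` residues are discarded; small
#' communities are prone to false correlations when few frames are
#' available.
#'
#' @param partition A `partition` from [louvain_partition()].
#' @param nodes Residue serials in partition order (e.g. `network$nodes`).
#' @param min_size Minimum residues per site (default 4).
#' @return Tibble `site_id` (provisional, by size), `residues` (list-column
#'   of residue serials), `n_residues`. Zero rows (with a warning) when no
#'   community passes the filter.
#' @export
filter_sites <- function(partition, nodes, min_size = 4L) {
  comm <- split(nodes, partition$membership)
  keep <- comm[vapply(comm, length, integer(1)) >= min_size]
  if (length(keep) == 0L) {
    warn("no community reaches min_size; no binding sites reported")
    return(tibble::tibble(
      site_id = integer(), residues = list(), n_residues = integer()
    ))
  }
  keep <- keep[order(-vapply(keep, length, integer(1)))]
  tibble::tibble(
    site_id = seq_along(keep),
    residues = lapply(unname(keep), sort),
    n_residues = vapply(keep, length, integer(1))
  )
}

# Elementwise-minimum distance of each ligand copy to the nearest residue
# of a site, per repeat: matrix [molecule, frame].
site_min_distances <- function(dml, site_residues) {
  mats <- dml[as.character(site_residues)]
  out <- mats[[1]]
  for (m in mats[-1]) out <- pmin(out, m)
  out
}

#' Site-level contact events
#'
#' A ligand copy is in contact with a site when its minimum distance to the
#' nearest site residue satisfies the dual-cutoff state machine. A molecule
#' hopping between residues of the same site without leaving it therefore
#' produces one site event.
#'
#' @param models A `system_model` or list of repeats.
#' @param site_residues Residue serials of the site.
#' @param cutoffs A [cutoff_pair()].
#' @param site_id Identifier copied onto the events.
#' @param dmls Optional precomputed list (per repeat) of distance matrix
#'   lists, to avoid recomputation.
#' @param n_workers Worker processes.
#' @return Event tibble as from [detect_events()], with a `site_id` column.
#' @export
site_events <- function(models, site_residues, cutoffs, site_id = NA_integer_,
                        dmls = NULL, n_workers = 1L) {
  if (inherits(models, "system_model")) models <- list(models)
  if (is.null(dmls)) {
    dmls <- lapply(models, distance_matrix_list, n_workers = n_workers)
  }
  ev <- dplyr::bind_rows(lapply(seq_along(models), function(ti) {
    mat <- site_min_distances(dmls[[ti]], site_residues)
    dplyr::bind_rows(lapply(seq_len(nrow(mat)), function(li) {
      detect_events(mat[li, ], cutoffs, models[[ti]]$dt,
        molecule_id = li, traj_id = models[[ti]]$traj_id
      )
    }))
  }))
  ev$site_id <- rep(site_id, nrow(ev))
  ev
}

# --- Shrake-Rupley accessible surface area ---------------------------------

# Deterministic quasi-uniform points on the unit sphere (golden spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Van der Waals radii (nm) by element; single-letter element guessed from
# the first alphabetic character of the atom name. Coarse-grained beads fall
# through to `default_radius`.
element_radii_nm <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180, P = 0.180,
  F = 0.147, B = 0.192
)

atom_radii <- function(atom_names, radii = element_radii_nm,
                       default_radius = 0.170) {
  el <- toupper(substr(gsub("[^A-Za-z].*$", "", atom_names), 1, 1))
  r <- unname(radii[el])
  r[is.na(r)] <- default_radius
  r
}

#' Shrake-Rupley accessible surface area
#'
#' Per-atom solvent-accessible surface area from sphere-point sampling:
#' each atom's sphere is inflated by the probe radius, `n_points` test
#' points are placed on it, and the accessible fraction is the share of
#' points not buried inside any neighbouring inflated sphere.
#'
#' @param xyz Matrix `n_atoms x 3` of coordinates (nm).
#' @param radii Per-atom van der Waals radii (nm).
#' @param probe_radius Probe radius in nm (default 0.14, a water-sized
#'   probe).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Numeric vector of per-atom areas (nm^2).
#' @export
shrake_rupley <- function(xyz, radii, probe_radius = 0.14, n_points = 960L) {
  n <- nrow(xyz)
  stopifnot(length(radii) == n)
  rr <- radii + probe_radius
  pts <- sphere_points(n_points)
  areas <- numeric(n)
  # neighbour prefilter on pairwise distances
  d2 <- as.matrix(dist(xyz))^2
  for (i in seq_len(n)) {
    cand <- which(d2[i, ] < (rr[i] + rr)^2 & seq_len(n) != i)
    p <- sweep(pts * rr[i], 2, xyz[i, ], `+`)
    if (length(cand) > 0L) {
      acc <- rep(TRUE, n_points)
      for (j in cand) {
        dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
          (p[, 3] - xyz[j, 3])^2
        acc <- acc & dj2 > rr[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else {
      frac <- 1
    }
    areas[i] <- 4 * pi * rr[i]^2 * frac
  }
  areas
}

#' Binding-site surface area over time
#'
#' Strips everything but the protein, runs Shrake-Rupley per frame, sums
#' atom areas per residue and the residue areas over the site.
#'
#' @param models A `system_model` or list of repeats.
#' @param site_residues Residue serials of the site.
#' @param probe_radius Probe radius (nm).
#' @param n_points Sphere points per atom.
#' @param radii Named element->radius table (nm).
#' @param default_radius Fallback radius for unknown elements/beads (nm).
#' @param frame_stride Compute every `frame_stride`-th frame.
#' @param n_workers Worker processes.
#' @return Tibble `traj_id`, `frame`, `time` (ns), `area` (nm^2).
#' @export
site_surface_area <- function(models, site_residues, probe_radius = 0.14,
                              n_points = 960L, radii = element_radii_nm,
                              default_radius = 0.170, frame_stride = 1L,
                              n_workers = 1L) {
  if (inherits(models, "system_model")) models <- list(models)
  dplyr::bind_rows(lapply(models, function(model) {
    prot_atoms <- unlist(model$residues$atom_indices)
    site_rows <- match(site_residues, model$residues$index)
    site_atoms <- unlist(model$residues$atom_indices[site_rows])
    r_all <- atom_radii(model$atoms$atom_name[prot_atoms],
      radii = radii, default_radius = default_radius
    )
    in_site <- prot_atoms %in% site_atoms
    frames <- seq(1L, model$n_frames, by = as.integer(frame_stride))
    vals <- ls_lapply(frames, function(k) {
      a <- shrake_rupley(model$coords[prot_atoms, , k],
        r_all,
        probe_radius = probe_radius, n_points = n_points
      )
      sum(a[in_site])
    }, n_workers = n_workers)
    tibble::tibble(
      traj_id = model$traj_id, frame = frames,
      time = (frames - 1L) * model$dt, area = unlist(vals)
    )
  }))
}
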