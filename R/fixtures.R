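# Synthetic trajectory generator with planted binding sites and known
# exponential dwell kinetics. Residues sit on a ring lattice (0.35 nm
# backbone spacing, roughly C-alpha-like); each planted site is a stretch of
# consecutive ring residues; each ligand copy is permanently assigned to one
# site and alternates between a bound state (its atoms laid along the site's
# arc, just outside the ring, with Gaussian jitter) and an unbound state far
# above the ring plane. Bound dwell times are Exp(koff_true), unbound gaps
# Exp(1/mean_unbound). Everything is written as GRO files so the real reader
# path is exercised.

#' Specification of a synthetic planted-site system
#'
#' @param n_residues Protein residues on the ring (2 pseudo-atoms each).
#' @param sites List of planted sites, each
#'   `list(residues = <consecutive serials>, koff = <true rate, ns^-1>)`.
#' @param n_ligands Ligand copies; copy `i` binds site `(i - 1) %% n_sites + 1`.
#' @param n_lig_atoms Atoms per ligand copy.
#' @param n_frames,dt Frames per repeat and time per frame (ns).
#' @param n_repeats Independent repeats (separate trajectories).
#' @param noise Positional jitter sd of the bound ligand atoms (nm).
#' @param mean_unbound Mean unbound dwell (ns).
#' @param box Cubic box edge (nm).
#' @param seed Integer seed.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_residues = 30L,
                         sites = list(
                           list(residues = 1:5, koff = 0.2),
                           list(residues = 11:15, koff = 0.5)
                         ),
                         n_ligands = 8L, n_lig_atoms = 4L,
                         n_frames = 3000L, dt = 0.5, n_repeats = 3L,
                         noise = 0.02, mean_unbound = 4,
                         box = 8, seed = 42L) {
  all_res <- unlist(lapply(sites, `[[`, "residues"))
  if (anyDuplicated(all_res)) stop_ls("planted residue sets must be disjoint")
  if (any(all_res > n_residues)) stop_ls("planted residues exceed n_residues")
  if (any(vapply(sites, `[[`, numeric(1), "koff") <= 0)) {
    stop_ls("koff_true must be positive")
  }
  structure(
    list(
      n_residues = n_residues, sites = sites, n_ligands = n_ligands,
      n_lig_atoms = n_lig_atoms, n_frames = n_frames, dt = dt,
      n_repeats = n_repeats, noise = noise, mean_unbound = mean_unbound,
      box = box, seed = seed
    ),
    class = "fixture_spec"
  )
}

# ring geometry shared by generator and feasibility check
fixture_geometry <- function(spec) {
  spacing <- 0.35
  radius <- spec$n_residues * spacing / (2 * pi)
  centre <- rep(spec$box / 2, 3)
  angles <- 2 * pi * (seq_len(spec$n_residues) - 1L) / spec$n_residues
  list(spacing = spacing, radius = radius, centre = centre, angles = angles)
}

# anchor positions of one ligand's atoms when bound at a site: spread evenly
# along the site's arc, 0.25 nm outside the ring
site_anchors <- function(spec, geo, site) {
  a <- geo$angles[range(site$residues)]
  th <- seq(a[1], a[2], length.out = spec$n_lig_atoms)
  r <- geo$radius + 0.25
  cbind(
    geo$centre[1] + r * cos(th),
    geo$centre[2] + r * sin(th),
    geo$centre[3]
  )
}

#' Generate a synthetic planted-site system
#'
#' Simulates the dwell-time process, writes topology + trajectory GRO files
#' and a ground-truth JSON into `dir`, reads them back through
#' [load_system()], and returns the models together with the truth record.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `models` (via the real reader), `truth` (per-ligand
#'   bound intervals in frames, per repeat, plus the planted sites), and the
#'   file `paths`.
#' @export
generate_fixture <- function(spec, dir = tempfile("fixture")) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geo <- fixture_geometry(spec)

  # feasibility: the ligand must be able to span its site's arc
  for (site in spec$sites) {
    arc <- geo$spacing * (length(site$residues) - 1L)
    reach <- geo$spacing * max(1L, spec$n_lig_atoms - 1L) + 2 * 0.475
    if (arc > reach) {
      stop_ls(
        "infeasible geometry: site arc %.2f nm exceeds ligand reach %.2f nm",
        arc, reach
      )
    }
  }

  # static protein coordinates: backbone bead on the ring, side bead inward
  n_res <- spec$n_residues
  prot_xyz <- matrix(NA_real_, n_res * 2L, 3L)
  for (i in seq_len(n_res)) {
    th <- geo$angles[i]
    bb <- c(geo$centre[1] + geo$radius * cos(th),
            geo$centre[2] + geo$radius * sin(th), geo$centre[3])
    sc <- c(geo$centre[1] + (geo$radius - 0.2) * cos(th),
            geo$centre[2] + (geo$radius - 0.2) * sin(th), geo$centre[3])
    prot_xyz[2L * i - 1L, ] <- bb
    prot_xyz[2L * i, ] <- sc
  }

  n_sites <- length(spec$sites)
  lig_site <- ((seq_len(spec$n_ligands) - 1L) %% n_sites) + 1L
  unbound_pos <- geo$centre + c(0, 0, 3)

  atoms <- tibble::tibble(
    resid = c(rep(seq_len(n_res), each = 2L), rep(n_res + seq_len(spec$n_ligands),
      each = spec$n_lig_atoms
    )),
    resname = c(rep("ALA", n_res * 2L), rep("LIG", spec$n_ligands * spec$n_lig_atoms)),
    atom_name = c(
      rep(c("BB", "SC1"), n_res),
      rep(sprintf("L%d", seq_len(spec$n_lig_atoms)), spec$n_ligands)
    )
  )

  traj_paths <- character(spec$n_repeats)
  truth_intervals <- list()
  for (rep_i in seq_len(spec$n_repeats)) {
    coords <- array(NA_real_, dim = c(nrow(atoms), 3L, spec$n_frames))
    for (k in seq_len(spec$n_frames)) coords[seq_len(n_res * 2L), , k] <- prot_xyz

    rep_truth <- list()
    for (li in seq_len(spec$n_ligands)) {
      site <- spec$sites[[lig_site[li]]]
      anchors <- site_anchors(spec, geo, site)
      # alternate unbound/bound dwell process, in frames
      bound_at <- with_seed(child_seed(spec$seed, rep_i * 1000L + li), {
        state <- logical(spec$n_frames)
        jit <- array(rnorm(spec$n_lig_atoms * 3L * spec$n_frames, sd = spec$noise),
          dim = c(spec$n_lig_atoms, 3L, spec$n_frames)
        )
        f <- 1L
        bound <- FALSE # start unbound
        while (f <= spec$n_frames) {
          mean_dwell <- if (bound) 1 / site$koff else spec$mean_unbound
          d <- max(1L, ceiling(rexp(1, 1 / mean_dwell) / spec$dt))
          state[f:min(spec$n_frames, f + d - 1L)] <- bound
          f <- f + d
          bound <- !bound
        }
        list(state = state, jit = jit)
      })
      lig_rows <- n_res * 2L + (li - 1L) * spec$n_lig_atoms + seq_len(spec$n_lig_atoms)
      for (k in seq_len(spec$n_frames)) {
        base <- if (bound_at$state[k]) anchors else {
          matrix(unbound_pos + c(li * 0.5, 0, 0),
            spec$n_lig_atoms, 3L,
            byrow = TRUE
          ) + geo$spacing * cbind(seq_len(spec$n_lig_atoms) - 1L, 0, 0)
        }
        coords[lig_rows, , k] <- base + bound_at$jit[, , k]
      }
      r <- rle(bound_at$state)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      rep_truth[[li]] <- tibble::tibble(
        traj_id = rep_i, molecule_id = li, site_id = lig_site[li],
        start_frame = starts[r$values], end_frame = ends[r$values]
      )
    }
    truth_intervals[[rep_i]] <- dplyr::bind_rows(rep_truth)

    traj_paths[rep_i] <- file.path(dir, sprintf("traj_%d.gro", rep_i))
    times_ps <- (seq_len(spec$n_frames) - 1L) * spec$dt * 1000
    write_gro(atoms, coords, rep(spec$box, 3), traj_paths[rep_i], times = times_ps)
    if (rep_i == 1L) {
      write_gro(atoms, coords[, , 1L], rep(spec$box, 3),
        file.path(dir, "topology.gro"),
        times = 0
      )
    }
  }

  truth <- list(
    sites = lapply(seq_along(spec$sites), function(s) {
      list(
        site_id = s, residues = spec$sites[[s]]$residues,
        koff_true = spec$sites[[s]]$koff
      )
    }),
    ligand_site = lig_site,
    intervals = dplyr::bind_rows(truth_intervals)
  )
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(
      sites = truth$sites, ligand_site = truth$ligand_site,
      intervals = truth$intervals
    ),
    truth_path,
    auto_unbox = TRUE, digits = NA
  )

  models <- load_system(
    trajectory_paths = traj_paths,
    topology_path = file.path(dir, "topology.gro"),
    ligand_name = "LIG"
  )
  list(
    models = models, truth = truth,
    paths = list(
      dir = dir, topology = file.path(dir, "topology.gro"),
      trajectories = traj_paths, truth = truth_path
    )
  )
}
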