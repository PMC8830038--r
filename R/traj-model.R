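# System model: topology + per-frame coordinates for one trajectory repeat.
# Coordinates in nm, times in ns, frames 1-based; rectangular boxes.

new_system_model <- function(atoms, coords, box, dt, residues, ligands,
                             traj_id = 1L) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  m <- structure(
    list(
      atoms = atoms, coords = coords, box = box, dt = dt,
      n_frames = dim(coords)[3], residues = residues, ligands = ligands,
      traj_id = traj_id
    ),
    class = "system_model"
  )
  validate_system_model(m)
}

validate_system_model <- function(m) {
  if (m$n_frames < 1L) stop_ls("system must have at least one frame")
  if (!is.numeric(m$dt) || m$dt <= 0) stop_ls("dt must be positive")
  idx <- c(
    unlist(m$residues$atom_indices),
    unlist(m$ligands$atom_indices)
  )
  if (anyDuplicated(idx)) stop_ls("atom indices shared between residues/ligands")
  if (length(idx) && (min(idx) < 1L || max(idx) > dim(m$coords)[1])) {
    stop_ls("atom index out of range")
  }
  for (i in seq_len(nrow(m$ligands))) {
    ca <- m$ligands$contact_atom_indices[[i]]
    if (length(ca) == 0L || !all(ca %in% m$ligands$atom_indices[[i]])) {
      stop_ls("ligand contact atoms must be a non-empty subset of its atoms")
    }
  }
  m
}

#' @export
print.system_model <- function(x, ...) {
  cat(sprintf(
    "<system_model> traj %s: %d frames (dt = %g ns), %d residues, %d ligand copies\n",
    x$traj_id, x$n_frames, x$dt, nrow(x$residues), nrow(x$ligands)
  ))
  invisible(x)
}

# --- selection grammar ------------------------------------------------------
# Minimal keyword grammar over the atom table:
#   "all" | "resname NAME ..." | "name ATOM ..." | "resid A B C-D ..."

parse_selection <- function(selection, atoms) {
  if (is.null(selection) || identical(selection, "all")) {
    return(rep(TRUE, nrow(atoms)))
  }
  tokens <- strsplit(trimws(selection), "\\s+")[[1]]
  key <- tokens[1]
  vals <- tokens[-1]
  if (length(vals) == 0L) stop_ls("selection '%s' names no values", selection)
  switch(key,
    resname = atoms$resname %in% vals,
    name = atoms$atom_name %in% vals,
    resid = {
      ids <- unlist(lapply(vals, function(v) {
        if (grepl("-", v, fixed = TRUE)) {
          ab <- as.integer(strsplit(v, "-", fixed = TRUE)[[1]])
          seq(ab[1], ab[2])
        } else {
          as.integer(v)
        }
      }))
      atoms$resid %in% ids
    },
    stop_ls("unknown selection keyword '%s' (use all/resname/name/resid)", key)
  )
}

# Group an atom table into consecutive residues (resid changes delimit).
residue_table <- function(atoms, mask) {
  sub <- atoms[mask, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(
      index = integer(), resid = integer(), resname = character(),
      chain = character(), atom_indices = list()
    ))
  }
  grp <- cumsum(c(1L, as.integer(diff(sub$resid) != 0L |
    head(sub$resname, -1) != tail(sub$resname, -1))))
  split_idx <- split(sub$atom_index, grp)
  firsts <- !duplicated(grp)
  tibble::tibble(
    index = seq_along(split_idx),
    resid = sub$resid[firsts],
    resname = sub$resname[firsts],
    chain = if ("chain" %in% names(sub)) sub$chain[firsts] else NA_character_,
    atom_indices = unname(split_idx)
  )
}

# --- readers ----------------------------------------------------------------

read_topology <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path)
    list(atoms = g$atoms, coords = g$coords[, , 1, drop = FALSE], box = g$box[1, ])
  } else if (ext == "pdb") {
    p <- bio3d::read.pdb(path)
    at <- p$atom
    atoms <- tibble::tibble(
      atom_index = seq_len(nrow(at)), resid = as.integer(at$resno),
      resname = trimws(at$resid), atom_name = trimws(at$elety),
      chain = ifelse(is.na(at$chain), "", at$chain)
    )
    xyz <- matrix(p$xyz[1, ], ncol = 3, byrow = TRUE) / 10 # A -> nm
    list(atoms = atoms, coords = array(xyz, dim = c(nrow(xyz), 3, 1)), box = NULL)
  } else {
    stop_ls("unsupported topology format '.%s' (use .gro or .pdb)", ext)
  }
}

read_trajectory <- function(path, topology) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    g <- read_gro(path)
    list(coords = g$coords, box = g$box, times_ps = g$times)
  } else if (ext == "pdb") {
    p <- bio3d::read.pdb(path, multi = TRUE)
    xyz <- p$xyz / 10
    n_at <- ncol(xyz) / 3
    coords <- array(NA_real_, dim = c(n_at, 3, nrow(xyz)))
    for (k in seq_len(nrow(xyz))) {
      coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    }
    list(coords = coords, box = NULL, times_ps = rep(NA_real_, nrow(xyz)))
  } else if (ext == "dcd") {
    xyz <- bio3d::read.dcd(path, verbose = FALSE) / 10
    n_at <- ncol(xyz) / 3
    coords <- array(NA_real_, dim = c(n_at, 3, nrow(xyz)))
    for (k in seq_len(nrow(xyz))) {
      coords[, , k] <- matrix(xyz[k, ], ncol = 3, byrow = TRUE)
    }
    list(coords = coords, box = NULL, times_ps = rep(NA_real_, nrow(xyz)))
  } else {
    stop_ls("unsupported trajectory format '.%s' (use .gro, .pdb or .dcd)", ext)
  }
}

#' Load trajectories into system models
#'
#' Reads one or more trajectory repeats against a shared topology, resolves
#' the ligand species and protein residues, and returns one `system_model`
#' per repeat. Repeats are never concatenated; downstream metrics combine
#' them at the event level.
#'
#' @param trajectory_paths Character vector of trajectory files (`.gro`
#'   multi-frame, `.pdb` multi-model, or `.dcd`).
#' @param topology_path Topology/coordinate file (`.gro` or `.pdb`). For
#'   `.dcd` trajectories the topology supplies the atom table.
#' @param ligand_name Residue name of the ligand species (e.g. `"CHOL"`).
#'   Every residue with this name becomes one ligand molecule.
#' @param protein_selection Optional selection string (`"all"`,
#'   `"resname ..."`, `"name ..."`, `"resid ..."`) restricting the protein
#'   residues analysed; applied to non-ligand atoms. Default: all of them.
#' @param ligand_atom_selection Optional selection string restricting which
#'   ligand atoms define contacts (e.g. `"name ROH"`). Default: all atoms.
#' @param stride Keep every `stride`-th frame.
#' @param dt_override Time per kept frame in ns; overrides the value
#'   inferred from frame time stamps.
#' @param exclude_hydrogens Drop atoms whose name starts with `H` from the
#'   protein residues (atomistic convenience; default keeps all atoms).
#' @return A list of `system_model` objects, one per trajectory, each with
#'   `$residues` and `$ligands` tibbles carrying resolved atom indices.
#' @export
load_system <- function(trajectory_paths, topology_path, ligand_name,
                        protein_selection = NULL,
                        ligand_atom_selection = NULL,
                        stride = 1L, dt_override = NULL,
                        exclude_hydrogens = FALSE) {
  top <- read_topology(topology_path)
  atoms <- top$atoms

  lig_mask <- atoms$resname == ligand_name
  if (!any(lig_mask)) stop_ls("ligand not found: no residue named '%s'", ligand_name)

  prot_mask <- !lig_mask & parse_selection(protein_selection, atoms)
  if (exclude_hydrogens) prot_mask <- prot_mask & !grepl("^H", atoms$atom_name)
  residues <- residue_table(atoms, prot_mask)
  if (nrow(residues) == 0L) stop_ls("protein selection matched no residues")

  lig_tab <- residue_table(atoms, lig_mask)
  contact_mask <- parse_selection(ligand_atom_selection, atoms)
  ligands <- tibble::tibble(
    molecule_id = seq_len(nrow(lig_tab)),
    resid = lig_tab$resid,
    atom_indices = lig_tab$atom_indices,
    contact_atom_indices = lapply(lig_tab$atom_indices, function(ix) {
      ix[contact_mask[ix]]
    })
  )
  bad <- vapply(ligands$contact_atom_indices, length, integer(1)) == 0L
  if (any(bad)) stop_ls("ligand_atom_selection matched no atoms of some ligand copies")

  models <- vector("list", length(trajectory_paths))
  for (ti in seq_along(trajectory_paths)) {
    tr <- read_trajectory(trajectory_paths[ti], top)
    if (dim(tr$coords)[1] != nrow(atoms)) {
      stop_ls(
        "atom count mismatch: topology has %d atoms, trajectory %s has %d",
        nrow(atoms), trajectory_paths[ti], dim(tr$coords)[1]
      )
    }
    keep <- seq(1L, dim(tr$coords)[3], by = as.integer(stride))
    coords <- tr$coords[, , keep, drop = FALSE]
    box <- if (!is.null(tr$box)) tr$box[keep, , drop = FALSE] else NULL
    dt <- dt_override
    if (is.null(dt)) {
      ts <- tr$times_ps[keep]
      dt <- if (length(ts) > 1L && !anyNA(ts)) (ts[2] - ts[1]) / 1000 else 1.0
    }
    models[[ti]] <- new_system_model(
      atoms, coords, box, dt, residues, ligands,
      traj_id = ti
    )
  }
  models
}

# --- distances --------------------------------------------------------------

# Minimum-image displacement for rectangular boxes; raw difference when no box.
min_image_delta <- function(delta, box_len) {
  if (is.null(box_len)) {
    return(delta)
  }
  delta - box_len * round(delta / box_len)
}

# Per-frame minimum distance between two atom index sets. box: n_frames x 3
# edge lengths or NULL.
pair_min_distance <- function(coords, box, atoms_a, atoms_b) {
  n_frames <- dim(coords)[3]
  best <- rep(Inf, n_frames)
  for (a in atoms_a) {
    for (b in atoms_b) {
      d2 <- rep(0, n_frames)
      for (k in 1:3) {
        delta <- coords[a, k, ] - coords[b, k, ]
        delta <- min_image_delta(delta, if (is.null(box)) NULL else box[, k])
        d2 <- d2 + delta * delta
      }
      best <- pmin(best, d2)
    }
  }
  sqrt(best)
}

#' Minimum ligand-residue distance per frame
#'
#' For one residue and one ligand copy, the per-frame minimum over all
#' (residue atom, ligand contact atom) pairs of the periodic minimum-image
#' distance (raw Euclidean when the model has no box).
#'
#' @param model A `system_model`.
#' @param residue_index Residue serial (row of `model$residues`).
#' @param molecule_id Ligand copy id (row of `model$ligands`).
#' @return A tibble with `frame`, `residue`, `molecule_id`, `distance` (nm).
#' @export
min_distance_series <- function(model, residue_index, molecule_id) {
  res <- model$residues[model$residues$index == residue_index, ]
  lig <- model$ligands[model$ligands$molecule_id == molecule_id, ]
  if (nrow(res) != 1L) stop_ls("residue %s not in model", residue_index)
  if (nrow(lig) != 1L) stop_ls("ligand copy %s not in model", molecule_id)
  d <- pair_min_distance(
    model$coords, model$box,
    res$atom_indices[[1]], lig$contact_atom_indices[[1]]
  )
  tibble::tibble(
    frame = seq_len(model$n_frames),
    residue = residue_index, molecule_id = molecule_id, distance = d
  )
}

# All residue x ligand minimum-distance series of one model as a matrix list:
# result[[residue]][molecule, frame]. Internal workhorse for contacts/sites.
distance_matrix_list <- function(model, n_workers = 1L) {
  res_ix <- model$residues$index
  out <- ls_lapply(res_ix, function(ri) {
    res_atoms <- model$residues$atom_indices[[which(model$residues$index == ri)]]
    mat <- matrix(NA_real_, nrow = nrow(model$ligands), ncol = model$n_frames)
    for (li in seq_len(nrow(model$ligands))) {
      mat[li, ] <- pair_min_distance(
        model$coords, model$box,
        res_atoms, model$ligands$contact_atom_indices[[li]]
      )
    }
    mat
  }, n_workers = n_workers)
  names(out) <- as.character(res_ix)
  out
}
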