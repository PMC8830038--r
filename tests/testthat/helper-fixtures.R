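# Shared test helpers: tiny in-code systems and independent oracles.

# Hand-built system: residues/ligands at given coordinates, constant over
# frames unless a coords array is supplied.
toy_system <- function(res_xyz_list, lig_xyz_list, n_frames = 1L,
                       box = NULL, dt = 1, coords_fun = NULL) {
  n_res_atoms <- sum(vapply(res_xyz_list, nrow, integer(1)))
  n_lig_atoms <- sum(vapply(lig_xyz_list, nrow, integer(1)))
  n_atoms <- n_res_atoms + n_lig_atoms
  base <- do.call(rbind, c(res_xyz_list, lig_xyz_list))
  coords <- array(NA_real_, dim = c(n_atoms, 3, n_frames))
  for (k in seq_len(n_frames)) {
    coords[, , k] <- if (is.null(coords_fun)) base else coords_fun(base, k)
  }
  res_sizes <- vapply(res_xyz_list, nrow, integer(1))
  lig_sizes <- vapply(lig_xyz_list, nrow, integer(1))
  res_ends <- cumsum(res_sizes)
  lig_ends <- n_res_atoms + cumsum(lig_sizes)
  atoms <- tibble::tibble(
    atom_index = seq_len(n_atoms),
    resid = c(
      rep(seq_along(res_sizes), res_sizes),
      rep(100L + seq_along(lig_sizes), lig_sizes)
    ),
    resname = c(rep("RES", n_res_atoms), rep("LIG", n_lig_atoms)),
    atom_name = paste0("A", seq_len(n_atoms))
  )
  residues <- tibble::tibble(
    index = seq_along(res_sizes),
    resid = seq_along(res_sizes), resname = "RES", chain = NA_character_,
    atom_indices = lapply(seq_along(res_sizes), function(i) {
      seq(res_ends[i] - res_sizes[i] + 1L, res_ends[i])
    })
  )
  ligands <- tibble::tibble(
    molecule_id = seq_along(lig_sizes),
    resid = 100L + seq_along(lig_sizes),
    atom_indices = lapply(seq_along(lig_sizes), function(i) {
      seq(lig_ends[i] - lig_sizes[i] + 1L, lig_ends[i])
    })
  )
  ligands$contact_atom_indices <- ligands$atom_indices
  box_mat <- if (is.null(box)) NULL else matrix(box, n_frames, 3, byrow = TRUE)
  lipidsite:::new_system_model(atoms, coords, box_mat, dt, residues, ligands)
}

# Independent hysteresis replay oracle: frame-by-frame two-state machine,
# written without reference to the implementation.
hysteresis_oracle <- function(values, lower, upper, dt = 1) {
  state <- FALSE
  events <- list()
  start <- NA_integer_
  for (i in seq_along(values)) {
    if (!state && values[i] < lower) {
      state <- TRUE
      start <- i
    } else if (state && values[i] >= upper) {
      events[[length(events) + 1L]] <- c(start, i - 1L)
      state <- FALSE
    }
  }
  if (state) events[[length(events) + 1L]] <- c(start, length(values))
  if (length(events) == 0L) {
    return(tibble::tibble(start_frame = integer(), end_frame = integer(), duration = numeric()))
  }
  m <- do.call(rbind, events)
  tibble::tibble(
    start_frame = m[, 1], end_frame = m[, 2],
    duration = (m[, 2] - m[, 1] + 1) * dt
  )
}

# Exhaustive window-counting survival oracle over events (frame units).
survival_oracle <- function(durations_frames, t_frames, lags) {
  raw <- vapply(lags, function(k) {
    tot <- 0
    for (d in durations_frames) {
      for (v in seq_len(max(0, t_frames - k))) { # window [v, v+k]
        tot <- tot + as.integer(v + k <= d)
      }
    }
    tot / (t_frames - k)
  }, numeric(1))
  raw / raw[1]
}

# Exhaustive modularity optimum over all partitions of <= 8 nodes.
all_partitions <- function(n) {
  if (n == 1L) {
    return(list(1L))
  }
  sub <- all_partitions(n - 1L)
  out <- list()
  for (p in sub) {
    for (c in seq_len(max(p) + 1L)) out[[length(out) + 1L]] <- c(p, c)
  }
  out
}

best_partition_oracle <- function(network) {
  n <- nrow(network$weights)
  best_q <- -Inf
  best_p <- NULL
  for (p in all_partitions(n)) {
    q <- modularity_q(network, p)
    if (q > best_q) {
      best_q <- q
      best_p <- p
    }
  }
  list(q = best_q, membership = best_p)
}

# Brute-force per-sample silhouette.
silhouette_oracle <- function(X, labels) {
  d <- as.matrix(dist(X))
  vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i] & seq_along(labels) != i)
    if (length(own) == 0L) {
      return(0)
    }
    a <- mean(d[i, own])
    b <- min(vapply(
      setdiff(unique(labels), labels[i]),
      function(cl) mean(d[i, labels == cl]), numeric(1)
    ))
    (b - a) / max(a, b)
  }, numeric(1))
}

small_fixture <- function(n_frames = 300L, seed = 42L, ...) {
  generate_fixture(
    fixture_spec(n_frames = n_frames, seed = seed, ...),
    dir = tempfile("lsfix")
  )
}
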