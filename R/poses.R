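# Bound-pose analysis. A pose is one ligand copy in one frame of a site
# event, expressed in relative-distance coordinates: the matrix D with
# D[i, p] = minimum distance of ligand atom i to site residue p (nm).
# These coordinates are invariant to rigid motion of protein + ligand, so
# pose analysis is independent of global and local protein displacement.

#' Collect bound poses of a binding site
#'
#' One pose per frame inside each site event. When the events hold more than
#' `max_poses` frames, an evenly spaced deterministic subset is kept so that
#' downstream kernel density scoring and clustering (both quadratic in the
#' pose count) stay tractable on long trajectories.
#'
#' @param models A `system_model` or list of repeats.
#' @param site_residues Residue serials of the site.
#' @param events Site-event tibble from [site_events()].
#' @param max_poses Upper bound on collected poses (default unlimited).
#' @return A `pose_set`: tibble `pose_id`, `traj_id`, `frame`,
#'   `molecule_id`, `D` (list-column of atom x residue distance matrices).
#' @export
collect_poses <- function(models, site_residues, events, max_poses = Inf) {
  if (inherits(models, "system_model")) models <- list(models)
  if (nrow(events) == 0L) {
    warn("no site events; returning empty pose set")
    return(empty_pose_set())
  }
  # enumerate all (traj, molecule, frame) pose slots, then subset
  slots <- dplyr::bind_rows(lapply(seq_len(nrow(events)), function(e) {
    tibble::tibble(
      traj_id = events$traj_id[e], molecule_id = events$molecule_id[e],
      frame = seq(events$start_frame[e], events$end_frame[e])
    )
  }))
  if (nrow(slots) > max_poses) {
    keep <- unique(round(seq(1L, nrow(slots), length.out = max_poses)))
    slots <- slots[keep, , drop = FALSE]
  }
  by_traj <- setNames(models, vapply(models, function(m) as.character(m$traj_id), ""))

  out <- slots |>
    dplyr::group_by(.data$traj_id, .data$molecule_id) |>
    dplyr::group_modify(function(grp, key) {
      model <- by_traj[[as.character(key$traj_id)]]
      lig <- model$ligands[model$ligands$molecule_id == key$molecule_id, ]
      lig_atoms <- lig$atom_indices[[1]]
      res_rows <- match(site_residues, model$residues$index)
      # full per-frame distance series per (ligand atom, site residue),
      # vectorized over frames, then subset to the kept pose frames
      Dser <- array(NA_real_, dim = c(length(lig_atoms), length(res_rows), model$n_frames))
      for (i in seq_along(lig_atoms)) {
        for (p in seq_along(res_rows)) {
          Dser[i, p, ] <- pair_min_distance(
            model$coords, model$box,
            lig_atoms[i], model$residues$atom_indices[[res_rows[p]]]
          )
        }
      }
      grp$D <- lapply(grp$frame, function(f) {
        matrix(Dser[, , f], nrow = length(lig_atoms), ncol = length(res_rows))
      })
      grp
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$traj_id, .data$molecule_id, .data$frame) |>
    dplyr::select("traj_id", "frame", "molecule_id", "D")
  out <- tibble::add_column(out, pose_id = seq_len(nrow(out)), .before = 1)
  class(out) <- c("pose_set", class(out))
  out
}

empty_pose_set <- function() {
  out <- tibble::tibble(
    pose_id = integer(), traj_id = integer(), frame = integer(),
    molecule_id = integer(), D = list()
  )
  class(out) <- c("pose_set", class(out))
  out
}

#' Construct a pose set from distance matrices
#'
#' For tests and simulation studies: wraps a list of atom x residue distance
#' matrices as a `pose_set` without a trajectory behind it.
#'
#' @param D_list List of matrices with identical dimensions.
#' @return A `pose_set`.
#' @export
pose_set <- function(D_list) {
  out <- tibble::tibble(
    pose_id = seq_along(D_list),
    traj_id = 1L, frame = seq_along(D_list), molecule_id = 1L,
    D = D_list
  )
  class(out) <- c("pose_set", class(out))
  out
}

# Stack one atom's relative-position vectors across poses: n_poses x p.
atom_coords_across_poses <- function(poses, atom_i) {
  do.call(rbind, lapply(poses$D, function(D) D[atom_i, ]))
}

# Gaussian product-kernel density of rows of `train` evaluated at rows of
# `query`; shared isotropic bandwidth h. Returns length-nrow(query) vector.
gaussian_kde <- function(train, query, h) {
  p <- ncol(train)
  norm_const <- (2 * pi)^(-p / 2) * h^(-p)
  vapply(seq_len(nrow(query)), function(q) {
    d2 <- rowSums(sweep(train, 2, query[q, ])^2)
    norm_const * mean(exp(-d2 / (2 * h^2)))
  }, numeric(1))
}

#' Score bound poses by kernel density
#'
#' Each ligand atom's relative position (its distance vector to the site
#' residues) gets a Gaussian kernel density estimate over all poses; a
#' pose's score is the atom-weight-weighted sum of its atoms' densities
#' evaluated at that pose. The highest-scoring pose is the most
#' representative bound pose.
#'
#' @param poses A `pose_set` with at least 2 poses (a single pose scores 0
#'   with a warning).
#' @param weights Per-atom weights `W_i >= 0` (default all 1; give head-group
#'   atoms more weight for lipids with floppy tails).
#' @param bandwidth Gaussian kernel bandwidth `H` in nm of the distance
#'   coordinates (default 0.15).
#' @param combine `"sum"` (default): `sum_i W_i f_i`; `"log_sum"`: `sum_i
#'   W_i log f_i`, i.e. a weighted product of densities.
#' @return The pose set with a `score` column appended.
#' @export
score_poses <- function(poses, weights = NULL, bandwidth = 0.15,
                        combine = c("sum", "log_sum")) {
  combine <- match.arg(combine)
  if (bandwidth <= 0) stop_ls("bandwidth must be positive")
  n <- nrow(poses)
  if (n == 0L) stop_ls("empty pose set")
  n_atoms <- nrow(poses$D[[1]])
  if (is.null(weights)) weights <- rep(1, n_atoms)
  if (length(weights) != n_atoms || any(weights < 0)) {
    stop_ls("weights must be %d non-negative values", n_atoms)
  }
  if (n == 1L) {
    warn("single pose: score undefined, set to 0")
    poses$score <- 0
    return(poses)
  }
  score <- rep(0, n)
  for (i in seq_len(n_atoms)) {
    if (weights[i] == 0) next
    X <- atom_coords_across_poses(poses, i)
    f <- gaussian_kde(X, X, bandwidth)
    score <- score + if (combine == "sum") weights[i] * f else weights[i] * log(f)
  }
  poses$score <- score
  poses
}

#' Representative bound pose
#'
#' The pose with the highest density score; ties broken by earliest
#' (`traj_id`, `frame`).
#'
#' @param poses A scored `pose_set` (see [score_poses()]).
#' @return The single winning pose row.
#' @export
representative_pose <- function(poses) {
  if (nrow(poses) == 0L) stop_ls("empty pose set")
  if (is.null(poses$score)) stop_ls("poses are not scored; run score_poses()")
  ord <- order(-poses$score, poses$traj_id, poses$frame)
  poses[ord[1], , drop = FALSE]
}

#' Write a pose with its protein conformation
#'
#' Writes the protein plus the bound ligand copy of one pose's source frame
#' to a `.gro` or `.pdb` file.
#'
#' @param pose One row of a scored `pose_set`.
#' @param models A `system_model` or list of repeats.
#' @param path Output file (`.gro` or `.pdb`).
#' @return `path`, invisibly.
#' @export
write_pose <- function(pose, models, path) {
  if (inherits(models, "system_model")) models <- list(models)
  model <- models[[which(vapply(models, function(m) m$traj_id, integer(1)) ==
    pose$traj_id)]]
  lig <- model$ligands[model$ligands$molecule_id == pose$molecule_id, ]
  atoms_ix <- c(unlist(model$residues$atom_indices), lig$atom_indices[[1]])
  at <- model$atoms[atoms_ix, ]
  xyz <- model$coords[atoms_ix, , pose$frame]
  ext <- tolower(tools::file_ext(path))
  if (ext == "gro") {
    box <- if (is.null(model$box)) c(0, 0, 0) else model$box[pose$frame, ]
    write_gro(at, xyz, box, path)
  } else if (ext == "pdb") {
    bio3d::write.pdb(
      file = path, xyz = as.numeric(t(xyz)) * 10,
      resno = at$resid, resid = at$resname, elety = at$atom_name
    )
  } else {
    stop_ls("unsupported pose format '.%s' (use .gro or .pdb)", ext)
  }
  invisible(path)
}

# Flatten pose D matrices to a n_poses x (atoms*residues) matrix.
pose_matrix <- function(poses) {
  do.call(rbind, lapply(poses$D, function(D) as.numeric(D)))
}

# PCA reduction keeping >= `var_keep` of variance, capped at `max_dim`.
pose_pca <- function(X, var_keep = 0.95, max_dim = 10L) {
  X <- X[, apply(X, 2, sd) > 0, drop = FALSE]
  if (ncol(X) == 0L) {
    return(matrix(0, nrow(X), 1L))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  v <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  d <- min(max(which(v >= var_keep)[1], 1L), max_dim, ncol(pc$x))
  pc$x[, seq_len(d), drop = FALSE]
}

#' Cluster poses with k-means
#'
#' Poses are flattened to their relative-distance coordinates, reduced by
#' PCA (keeping 95% variance, at most 10 components), and clustered with
#' Lloyd-iteration k-means; one randomly chosen pose per cluster is marked
#' as that cluster's exemplar.
#'
#' @param poses A `pose_set`.
#' @param n_clusters Number of clusters (must not exceed the pose count).
#' @param seed Integer seed (k-means starts and exemplar draws).
#' @param nstart Random restarts for k-means.
#' @return A `pose_clustering`: list with `method`, `labels`, `inertia`,
#'   `silhouette`, `exemplars` (pose ids), `reduced` (PCA coordinates).
#' @export
cluster_kmeans <- function(poses, n_clusters, seed = 1L, nstart = 10L) {
  n <- nrow(poses)
  if (n_clusters > n) stop_ls("n_clusters (%d) exceeds pose count (%d)", n_clusters, n)
  X <- pose_pca(pose_matrix(poses))
  if (n_clusters == n) {
    # every pose its own cluster; stats::kmeans rejects this boundary case
    res <- list(cluster = seq_len(n), tot.withinss = 0)
  } else {
    res <- with_seed(seed, kmeans(X, centers = n_clusters, nstart = nstart, iter.max = 100))
  }
  labels <- unname(res$cluster)
  sil <- silhouette_mean(X, labels)
  exemplars <- with_seed(child_seed(seed, 1L), vapply(
    sort(unique(labels)),
    function(cl) {
      ix <- which(labels == cl)
      poses$pose_id[ix[sample.int(length(ix), 1L)]]
    }, numeric(1)
  ))
  structure(
    list(
      method = "kmeans", labels = labels, inertia = res$tot.withinss,
      silhouette = sil, exemplars = as.integer(exemplars),
      n_clusters = n_clusters, reduced = X
    ),
    class = "pose_clustering"
  )
}

# mean silhouette over all points; NA when fewer than 2 clusters
silhouette_mean <- function(X, labels, d = NULL) {
  ok <- labels > 0
  n_cl <- length(unique(labels[ok]))
  if (n_cl < 2L || sum(ok) < 3L || n_cl >= sum(ok)) {
    return(NA_real_) # undefined for <2 clusters or all-singleton labellings
  }
  dd <- if (is.null(d)) dist(X[ok, , drop = FALSE]) else stats::as.dist(as.matrix(d)[ok, ok])
  mean(cluster::silhouette(labels[ok], dd)[, "sil_width"])
}

# Sorted k-nearest-neighbour distance curve knee by the max-distance-to-chord
# (triangle) method; returns the knee value.
knee_point <- function(sorted_vals) {
  n <- length(sorted_vals)
  if (n < 3L) {
    return(sorted_vals[n])
  }
  x <- seq_len(n)
  x1 <- 1
  y1 <- sorted_vals[1]
  x2 <- n
  y2 <- sorted_vals[n]
  # distance of each point to the chord from first to last point
  num <- abs((y2 - y1) * x - (x2 - x1) * sorted_vals + x2 * y1 - y2 * x1)
  sorted_vals[which.max(num)]
}

# Plain DBSCAN on a precomputed distance matrix. Labels: 0 = noise.
dbscan_labels <- function(dmat, eps, min_samples) {
  n <- nrow(dmat)
  neighbours <- lapply(seq_len(n), function(i) which(dmat[i, ] <= eps))
  core <- vapply(neighbours, length, integer(1)) >= min_samples
  labels <- rep(0L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- neighbours[[i]]
    while (length(frontier) > 0L) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, neighbours[[j]][labels[neighbours[[j]]] == 0L])
      }
    }
  }
  list(labels = labels, core = core)
}

#' Cluster poses with DBSCAN
#'
#' Unsupervised pose clustering: `eps` is set to the knee of the sorted
#' k-distance curve (k = `min_samples_init`), then `min_samples` is scanned
#' and the labelling with the highest mean silhouette (over non-noise
#' points) is returned. Exemplars are one core sample per cluster.
#'
#' @param poses A `pose_set` with at least 4 poses.
#' @param min_samples_init k for the k-distance curve (default 4).
#' @param min_samples_range Candidate `min_samples` values; default
#'   `3:min(20, n_poses - 1)`.
#' @param eps Neighbourhood radius; `NULL` (default) sets it automatically
#'   from the knee of the k-distance curve.
#' @param seed Seed for the exemplar draw.
#' @return A `pose_clustering` with `eps`, `min_samples`, noise allowed as
#'   label 0; `all_noise` flags a degenerate result.
#' @export
cluster_dbscan <- function(poses, min_samples_init = 4L,
                           min_samples_range = NULL, eps = NULL, seed = 1L) {
  n <- nrow(poses)
  if (n < 4L) stop_ls("DBSCAN needs at least 4 poses, got %d", n)
  X <- pose_pca(pose_matrix(poses))
  dmat <- as.matrix(dist(X))
  if (is.null(eps)) {
    k <- min(min_samples_init, n - 1L)
    kdist <- sort(apply(dmat, 1, function(r) sort(r)[k + 1L]))
    eps <- knee_point(kdist)
  }
  if (is.null(min_samples_range)) min_samples_range <- 3:min(20L, n - 1L)

  best <- NULL
  for (ms in min_samples_range) {
    fit <- dbscan_labels(dmat, eps, ms)
    s <- silhouette_mean(X, fit$labels, d = dmat)
    if (is.null(best) || (!is.na(s) && (is.na(best$s) || s > best$s))) {
      best <- list(labels = fit$labels, core = fit$core, s = s, ms = ms)
    }
  }
  all_noise <- all(best$labels == 0L)
  if (all_noise) warn("DBSCAN labelled every pose as noise")
  exemplars <- integer()
  if (!all_noise) {
    exemplars <- with_seed(child_seed(seed, 2L), vapply(
      sort(unique(best$labels[best$labels > 0L])),
      function(cl) {
        ix <- which(best$labels == cl & best$core)
        if (length(ix) == 0L) ix <- which(best$labels == cl)
        poses$pose_id[ix[sample.int(length(ix), 1L)]]
      }, numeric(1)
    ))
  }
  structure(
    list(
      method = "dbscan", labels = best$labels, eps = eps,
      min_samples = best$ms, silhouette = best$s,
      inertia = NA_real_, exemplars = as.integer(exemplars),
      all_noise = all_noise, reduced = X
    ),
    class = "pose_clustering"
  )
}

#' @export
print.pose_clustering <- function(x, ...) {
  k <- length(unique(x$labels[x$labels > 0]))
  cat(sprintf(
    "<pose_clustering> %s: %d cluster(s), silhouette %.3f%s\n",
    x$method, k, x$silhouette,
    if (x$method == "dbscan") sprintf(", eps %.3g, %d noise", x$eps, sum(x$labels == 0)) else ""
  ))
  invisible(x)
}

#' Pose RMSD about the mean bound pose
#'
#' For each pose, `sqrt(sum_i ||D_i - Dbar_i||^2 / N)` where `Dbar_i` is the
#' across-pose mean relative-position vector of ligand atom i and N the
#' ligand atom count. Zero iff all poses coincide.
#'
#' @param poses A `pose_set`.
#' @return Tibble `pose_id`, `rmsd` (nm), with attributes `mean` and `sd`.
#' @export
pose_rmsd <- function(poses) {
  n <- nrow(poses)
  if (n == 0L) stop_ls("empty pose set")
  Dbar <- Reduce(`+`, poses$D) / n
  n_atoms <- nrow(Dbar)
  rmsd <- vapply(poses$D, function(D) {
    sqrt(sum((D - Dbar)^2) / n_atoms)
  }, numeric(1))
  out <- tibble::tibble(pose_id = poses$pose_id, rmsd = rmsd)
  attr(out, "mean") <- mean(rmsd)
  attr(out, "sd") <- if (n > 1L) sd(rmsd) else 0
  out
}
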