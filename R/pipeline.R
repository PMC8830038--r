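# Single-call pipeline: load -> residue contacts/koff -> binding sites ->
# site koff -> poses -> surface areas -> outputs. Stage order is fixed;
# individual stages can be skipped; results are deterministic for a given
# config + seed and independent of the worker count.

#' Pipeline configuration
#'
#' Validates and normalises all pipeline options before any computation.
#'
#' @param trajectories Character vector of trajectory paths.
#' @param topology Topology path.
#' @param ligand Ligand residue name.
#' @param ligand_atoms Optional ligand contact-atom selection string.
#' @param protein_selection Optional protein selection string.
#' @param stride Frame stride on load.
#' @param dt_override Frame time override (ns).
#' @param cutoffs Length-2 numeric `(lower, upper)` in nm. The defaults
#'   0.475/0.8 nm are the values used for coarse-grained cholesterol
#'   analysis; atomistic systems typically need smaller values.
#' @param min_site_size Minimum residues per binding site.
#' @param features Correlation features, `"binary"` or `"distance"`.
#' @param bandwidth Pose-scoring kernel bandwidth (nm).
#' @param max_poses Cap on poses collected per site (evenly spaced subset
#'   beyond it); density scoring and clustering are quadratic in this.
#' @param pose_weights Optional per-atom pose weights.
#' @param n_boot Bootstrap replicates for koff.
#' @param lag_stride Survival-function lag stride.
#' @param probe_radius,sasa_points,sasa_stride Shrake-Rupley parameters.
#' @param pose_format `"gro"` or `"pdb"` for written poses.
#' @param pose_clustering `"dbscan"`, `"kmeans"` or `"none"`.
#' @param kmeans_clusters Cluster count when `pose_clustering = "kmeans"`.
#' @param skip_poses,skip_sasa Skip the pose / surface-area stages.
#' @param output_dir Output tree root.
#' @param n_workers Worker processes for parallelisable stages.
#' @param seed Master seed.
#' @return A validated `run_config` list.
#' @export
run_config <- function(trajectories, topology, ligand,
                       ligand_atoms = NULL, protein_selection = NULL,
                       stride = 1L, dt_override = NULL,
                       cutoffs = c(0.475, 0.8), min_site_size = 4L,
                       features = "binary", bandwidth = 0.15,
                       max_poses = 1000L, pose_weights = NULL, n_boot = 10L, lag_stride = 1L,
                       probe_radius = 0.14, sasa_points = 960L,
                       sasa_stride = 1L, pose_format = "gro",
                       pose_clustering = "dbscan", kmeans_clusters = 2L,
                       skip_poses = FALSE, skip_sasa = FALSE,
                       output_dir = "lipidsite_output", n_workers = 1L,
                       seed = 1L) {
  missing_files <- c(trajectories, topology)[!file.exists(c(trajectories, topology))]
  if (length(missing_files) > 0L) {
    stop_ls("input file(s) not found: %s", paste(missing_files, collapse = ", "))
  }
  cp <- cutoff_pair(cutoffs[1], cutoffs[2]) # validates
  stopifnot(
    min_site_size >= 1L, bandwidth > 0, n_boot >= 0L,
    probe_radius >= 0, sasa_points >= 12L,
    features %in% c("binary", "distance"),
    pose_format %in% c("gro", "pdb"),
    pose_clustering %in% c("dbscan", "kmeans", "none")
  )
  structure(
    list(
      trajectories = trajectories, topology = topology, ligand = ligand,
      ligand_atoms = ligand_atoms, protein_selection = protein_selection,
      stride = as.integer(stride), dt_override = dt_override,
      cutoffs = cp, min_site_size = as.integer(min_site_size),
      features = features, bandwidth = bandwidth,
      max_poses = max_poses, pose_weights = pose_weights, n_boot = as.integer(n_boot),
      lag_stride = as.integer(lag_stride), probe_radius = probe_radius,
      sasa_points = as.integer(sasa_points),
      sasa_stride = as.integer(sasa_stride), pose_format = pose_format,
      pose_clustering = pose_clustering,
      kmeans_clusters = as.integer(kmeans_clusters),
      skip_poses = isTRUE(skip_poses), skip_sasa = isTRUE(skip_sasa),
      output_dir = output_dir, n_workers = as.integer(n_workers),
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline config from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; `overrides` (e.g. parsed
#' command-line flags) win over file values.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}

site_frame_index <- function(dmls, sites_tbl, cutoffs) {
  lapply(seq_along(dmls), function(ti) {
    dplyr::bind_rows(lapply(seq_len(nrow(sites_tbl)), function(s) {
      mat <- site_min_distances(dmls[[ti]], sites_tbl$residues[[s]])
      hit <- which(mat < cutoffs$lower, arr.ind = TRUE)
      if (nrow(hit) == 0L) {
        return(NULL)
      }
      tibble::tibble(
        residue = sites_tbl$site_id[s], frame = as.integer(hit[, 2]),
        molecule_id = as.integer(hit[, 1])
      )
    }))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the complete workflow and writes the output tree:
#' `dataset.csv` (master residue table), `coordinates_residence_time.pdb`
#' (B-factor annotated), `show_sites.py` (viewer script),
#' `interactions_*.csv/png`, `run_config.yml`, and per-site directories
#' `sites/<id>/` with `summary.txt`, `koff.csv`, `surface_area.csv`,
#' `rmsd.csv` and written poses.
#'
#' @param config A `run_config`.
#' @return Invisibly, a list with the residue `table`, `sites` tibble,
#'   `site_fits`, `models` and the `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  cfg_plain <- config
  cfg_plain$cutoffs <- c(config$cutoffs$lower, config$cutoffs$upper)
  yaml::write_yaml(cfg_plain[!vapply(cfg_plain, is.null, logical(1))],
    file.path(out, "run_config.yml"))

  models <- load_system(
    config$trajectories, config$topology, config$ligand,
    protein_selection = config$protein_selection,
    ligand_atom_selection = config$ligand_atoms,
    stride = config$stride, dt_override = config$dt_override
  )
  dt <- models[[1]]$dt
  T_total <- max(vapply(models, function(m) m$n_frames * m$dt, numeric(1)))

  dmls <- lapply(models, distance_matrix_list, n_workers = config$n_workers)

  # residue contacts + metrics
  events <- dplyr::bind_rows(lapply(seq_along(models), function(ti) {
    dml <- dmls[[ti]]
    dplyr::bind_rows(lapply(names(dml), function(rn) {
      dplyr::bind_rows(lapply(seq_len(nrow(dml[[rn]])), function(li) {
        detect_events(dml[[rn]][li, ], config$cutoffs, models[[ti]]$dt,
          residue = as.integer(rn), molecule_id = li,
          traj_id = models[[ti]]$traj_id
        )
      }))
    }))
  }))
  frame_index <- lapply(dmls, frame_contact_index, cutoffs = config$cutoffs)
  metrics <- residue_metrics(events, frame_index,
    residues = models[[1]]$residues$index
  )

  # residue kinetics
  res_fit_rows <- dplyr::bind_rows(lapply(models[[1]]$residues$index, function(ri) {
    ev <- events[events$residue == ri, , drop = FALSE]
    if (nrow(ev) == 0L) {
      return(tibble::tibble(
        residue = ri, koff = NA_real_, residence_time = NA_real_,
        r_squared = NA_real_, koff_boot_mean = NA_real_, koff_boot_sd = NA_real_
      ))
    }
    fit <- compute_koff(ev, T_total, dt,
      n_boot = config$n_boot,
      seed = child_seed(config$seed, ri), lag_stride = config$lag_stride
    )
    g <- glance(fit)
    tibble::tibble(
      residue = ri, koff = g$koff, residence_time = g$residence_time,
      r_squared = g$r_squared, koff_boot_mean = g$boot_koff_mean,
      koff_boot_sd = g$boot_koff_sd
    )
  }))

  # binding sites
  network <- build_network(models, config$cutoffs,
    features = config$features, n_workers = config$n_workers
  )
  partition <- louvain_partition(network, seed = config$seed)
  sites_tbl <- filter_sites(partition, network$nodes,
    min_size = config$min_site_size
  )

  site_fits <- list()
  site_rows <- list()
  if (nrow(sites_tbl) > 0L) {
    sev_all <- lapply(seq_len(nrow(sites_tbl)), function(s) {
      site_events(models, sites_tbl$residues[[s]], config$cutoffs,
        site_id = sites_tbl$site_id[s], dmls = dmls
      )
    })
    sfi <- site_frame_index(dmls, sites_tbl, config$cutoffs)
    for (k in seq_along(sfi)) attr(sfi[[k]], "n_frames") <- models[[k]]$n_frames
    smet <- residue_metrics(
      dplyr::bind_rows(sev_all) |> dplyr::mutate(residue = .data$site_id),
      sfi,
      residues = sites_tbl$site_id
    )
    for (s in seq_len(nrow(sites_tbl))) {
      sev <- sev_all[[s]]
      fit <- if (nrow(sev) > 0L) {
        compute_koff(sev, T_total, dt,
          n_boot = config$n_boot,
          seed = child_seed(config$seed, 10000L + s),
          lag_stride = config$lag_stride
        )
      } else {
        NULL
      }
      site_fits[[s]] <- fit
      g <- if (is.null(fit)) NULL else glance(fit)
      m <- smet[smet$residue == sites_tbl$site_id[s], ]
      site_rows[[s]] <- tibble::tibble(
        site_id = sites_tbl$site_id[s],
        site_mean_duration = m$mean_duration,
        site_occupancy = m$occupancy,
        site_lipid_count = m$lipid_count,
        site_koff = if (is.null(g)) NA_real_ else g$koff,
        site_residence_time = if (is.null(g)) NA_real_ else g$residence_time,
        site_r_squared = if (is.null(g)) NA_real_ else g$r_squared
      )
    }
    site_summary <- dplyr::bind_rows(site_rows)

    # rank sites by descending residence time and relabel 1..n
    rt_rank <- site_summary$site_residence_time
    rt_rank[is.na(rt_rank)] <- -1 # unfitted sites rank last; Inf ranks first
    ord <- order(-rt_rank)
    relabel <- match(seq_len(nrow(sites_tbl)), ord)
    sites_tbl$site_id <- relabel
    site_summary$site_id <- relabel
    for (s in seq_along(sev_all)) sev_all[[s]]$site_id <- relabel[s]
    new_order <- order(sites_tbl$site_id)
    sites_tbl <- sites_tbl[new_order, ]
    site_summary <- site_summary[new_order, ]
    sev_all <- sev_all[new_order]
    site_fits <- site_fits[new_order]
    sites_tbl <- dplyr::bind_cols(
      sites_tbl,
      site_summary[match(sites_tbl$site_id, site_summary$site_id), -1]
    )
    names(sites_tbl) <- sub("^site_", "", names(sites_tbl))
    names(sites_tbl)[names(sites_tbl) == "id"] <- "site_id"
  }

  # master table
  table <- models[[1]]$residues |>
    dplyr::select("index", "resid", "resname", "chain") |>
    dplyr::rename(residue = "index") |>
    dplyr::left_join(metrics, by = "residue") |>
    dplyr::left_join(res_fit_rows, by = "residue")
  site_of <- rep(NA_integer_, nrow(table))
  if (nrow(sites_tbl) > 0L) {
    for (s in seq_len(nrow(sites_tbl))) {
      site_of[table$residue %in% sites_tbl$residues[[s]]] <- sites_tbl$site_id[s]
    }
  }
  table$site_id <- site_of
  if (nrow(sites_tbl) > 0L) {
    table <- dplyr::left_join(
      table,
      sites_tbl |>
        dplyr::select(-"residues", -"n_residues") |>
        dplyr::rename_with(~ paste0("site_", .x), -"site_id"),
      by = "site_id"
    )
  }

  write_table(table, file.path(out, "dataset.csv"))
  rt <- setNames(table$residence_time, table$residue)
  rt[!is.finite(rt)] <- 0
  pdb_path <- file.path(out, "coordinates_residence_time.pdb")
  write_bfactor_coordinates(models[[1]], rt, pdb_path)
  write_visualization_script(sites_tbl, table, pdb_path,
    file.path(out, "show_sites.py"),
    metric = "residence_time"
  )
  plot_interactions(table, "occupancy", file.path(out, "interactions_occupancy.png"))

  # per-site products
  if (nrow(sites_tbl) > 0L) {
    for (s in seq_len(nrow(sites_tbl))) {
      sdir <- file.path(out, "sites", sites_tbl$site_id[s])
      dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
      fit <- site_fits[[s]]
      if (!is.null(fit)) {
        curve <- fit$curve
        readr::write_csv(
          tibble::tibble(
            t = curve$t, sigma = curve$sigma,
            fitted = fit$A * exp(-fit$k1 * curve$t) +
              fit$B * exp(-fit$k2 * curve$t)
          ),
          file.path(sdir, "koff.csv")
        )
      }

      area_summary <- c(mean = NA_real_, sd = NA_real_)
      if (!config$skip_sasa) {
        area <- site_surface_area(models, sites_tbl$residues[[s]],
          probe_radius = config$probe_radius, n_points = config$sasa_points,
          frame_stride = config$sasa_stride, n_workers = config$n_workers
        )
        readr::write_csv(area, file.path(sdir, "surface_area.csv"))
        area_summary <- c(mean = mean(area$area), sd = sd(area$area))
      }

      if (!config$skip_poses && nrow(sev_all[[s]]) > 0L) {
        poses <- collect_poses(models, sites_tbl$residues[[s]], sev_all[[s]],
          max_poses = config$max_poses
        )
        poses <- score_poses(poses,
          weights = config$pose_weights,
          bandwidth = config$bandwidth
        )
        pdir <- file.path(sdir, "poses")
        dir.create(pdir, showWarnings = FALSE)
        rep_pose <- representative_pose(poses)
        write_pose(rep_pose, models, file.path(
          pdir, paste0("representative.", config$pose_format)
        ))
        if (config$pose_clustering != "none" && nrow(poses) >= 4L) {
          cl <- if (config$pose_clustering == "kmeans") {
            cluster_kmeans(poses,
              n_clusters = min(config$kmeans_clusters, nrow(poses)),
              seed = child_seed(config$seed, 20000L + s)
            )
          } else {
            cluster_dbscan(poses, seed = child_seed(config$seed, 20000L + s))
          }
          for (ex in cl$exemplars) {
            write_pose(
              poses[poses$pose_id == ex, ], models,
              file.path(pdir, sprintf("cluster_%d.%s", which(cl$exemplars == ex),
                config$pose_format
              ))
            )
          }
        }
        rmsd <- pose_rmsd(poses)
        readr::write_csv(rmsd, file.path(sdir, "rmsd.csv"))
      }

      write_site_info(
        sites_tbl[s, ],
        fit %||% new_koff_fit(NA, NA, NA, NA, NA,
          curve = tibble::tibble(t = 0, sigma = 1), converged = FALSE
        ),
        area_summary, file.path(sdir, "summary.txt")
      )
    }
  }

  invisible(list(
    table = table, sites = sites_tbl, site_fits = site_fits,
    network = network, partition = partition,
    events = events, models = models, output_dir = out
  ))
}
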