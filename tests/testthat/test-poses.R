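cp_default <- cutoff_pair(0.475, 0.8)

# Gaussian blobs of D matrices around a centre value
blob_poses <- function(mu, n, n_atoms = 2, n_res = 4, sd = 0.05) {
  lapply(seq_len(n), function(i) {
    matrix(abs(rnorm(n_atoms * n_res, mu, sd)), n_atoms, n_res)
  })
}

test_that("collect_poses yields one pose per event frame with brute-force D", {
  fx <- small_fixture(n_frames = 40, seed = 6, n_repeats = 1)
  m <- fx$models[[1]]
  site_res <- 1:5
  sev <- site_events(m, site_res, cp_default, site_id = 1L)
  poses <- collect_poses(m, site_res, sev)
  expect_equal(nrow(poses), sum(sev$end_frame - sev$start_frame + 1))

  # brute-force D for one pose
  p1 <- poses[1, ]
  lig <- m$ligands[m$ligands$molecule_id == p1$molecule_id, ]
  lig_atoms <- lig$atom_indices[[1]]
  D_oracle <- matrix(NA_real_, length(lig_atoms), length(site_res))
  for (i in seq_along(lig_atoms)) {
    for (p in seq_along(site_res)) {
      res_atoms <- m$residues$atom_indices[[site_res[p]]]
      dmin <- Inf
      for (ra in res_atoms) {
        d <- sqrt(sum((m$coords[lig_atoms[i], , p1$frame] - m$coords[ra, , p1$frame])^2))
        dmin <- min(dmin, d)
      }
      D_oracle[i, p] <- dmin
    }
  }
  expect_equal(p1$D[[1]], D_oracle, tolerance = 1e-10)
  expect_true(all(p1$D[[1]] >= 0))
})

test_that("relative-distance coordinates are invariant to rigid translation", {
  res_xyz <- matrix(runif(9, 1, 2), 3, 3)
  lig_xyz <- matrix(runif(6, 1, 2), 2, 3)
  mk <- function(shift) {
    toy_system(
      list(sweep(res_xyz, 2, shift, `+`)),
      list(sweep(lig_xyz, 2, shift, `+`))
    )
  }
  ev <- tibble::tibble(
    traj_id = 1L, molecule_id = 1L, start_frame = 1L, end_frame = 1L
  )
  D0 <- collect_poses(mk(c(0, 0, 0)), 1:3, ev)$D[[1]]
  D1 <- collect_poses(mk(c(5, -2, 3)), 1:3, ev)$D[[1]]
  expect_equal(D0, D1, tolerance = 1e-10)
})

test_that("KDE scores pick the dominant pose mode and respect weights", {
  set.seed(5)
  ps <- pose_set(c(blob_poses(0.5, 90), blob_poses(2.0, 10)))
  scored <- score_poses(ps)
  rep_pose <- representative_pose(scored)
  expect_lt(mean(scored$D[[rep_pose$pose_id]]), 1) # from the 90% mode

  # identical poses score identically
  same <- score_poses(pose_set(rep(list(matrix(0.4, 2, 3)), 5)))
  expect_equal(length(unique(same$score)), 1)

  # zero-weight atoms do not influence scores
  ps2 <- pose_set(blob_poses(0.6, 20))
  ps2_mod <- ps2
  ps2_mod$D <- lapply(seq_len(20), function(i) {
    D <- ps2$D[[i]]
    D[2, ] <- runif(ncol(D), 0, 5) # scramble atom 2
    D
  })
  s_a <- score_poses(ps2, weights = c(1, 0))$score
  s_b <- score_poses(ps2_mod, weights = c(1, 0))$score
  expect_equal(s_a, s_b, tolerance = 1e-12)

  # single pose: flagged zero score
  expect_warning(s1 <- score_poses(pose_set(blob_poses(0.5, 1))), "single pose")
  expect_equal(s1$score, 0)
})

test_that("scores agree with an exhaustive KDE evaluation", {
  set.seed(9)
  ps <- pose_set(blob_poses(0.8, 15, n_atoms = 2, n_res = 3))
  h <- 0.15
  scored <- score_poses(ps, bandwidth = h)
  # direct double-loop Gaussian product KDE
  oracle <- vapply(seq_len(15), function(q) {
    tot <- 0
    for (i in 1:2) {
      x <- ps$D[[q]][i, ]
      dens <- mean(vapply(seq_len(15), function(j) {
        d2 <- sum((ps$D[[j]][i, ] - x)^2)
        (2 * pi)^(-3 / 2) * h^(-3) * exp(-d2 / (2 * h^2))
      }, numeric(1)))
      tot <- tot + dens
    }
    tot
  }, numeric(1))
  expect_equal(scored$score, oracle, tolerance = 1e-12)
})

test_that("bandwidth smoothing shrinks score variance; ties break by frame order", {
  set.seed(15)
  ps <- pose_set(blob_poses(0.7, 30))
  v <- vapply(c(0.05, 0.15, 0.5, 1.5), function(h) {
    var(score_poses(ps, bandwidth = h)$score)
  }, numeric(1))
  expect_true(all(diff(v) < 0))

  tie <- score_poses(pose_set(rep(list(matrix(0.3, 2, 2)), 3)))
  rp <- representative_pose(tie)
  expect_equal(rp$pose_id, 1L) # earliest frame wins the tie
})

test_that("kmeans clustering recovers separated blobs and the exhaustive optimum", {
  set.seed(20)
  ps <- pose_set(c(blob_poses(0.5, 3), blob_poses(3.0, 3)))
  cl <- cluster_kmeans(ps, 2, seed = 1)
  expect_equal(cl$labels[1:3], rep(cl$labels[1], 3))
  expect_equal(cl$labels[4:6], rep(cl$labels[4], 3))
  expect_true(cl$labels[1] != cl$labels[4])

  # exhaustive 2-partition optimum on the PCA coordinates
  X <- cl$reduced
  best <- Inf
  for (mask in 1:(2^6 - 2)) {
    g <- as.logical(bitwAnd(mask, 2^(0:5)))
    if (!any(g) || all(g)) next
    inertia <- sum(scale(X[g, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(X[!g, , drop = FALSE], scale = FALSE)^2)
    best <- min(best, inertia)
  }
  expect_equal(cl$inertia, best, tolerance = 1e-8)

  # n = n_poses gives zero inertia
  cl0 <- cluster_kmeans(ps, 6, seed = 1)
  expect_equal(cl0$inertia, 0, tolerance = 1e-12)
  expect_error(cluster_kmeans(ps, 7, seed = 1), "exceeds pose count")
})

test_that("dbscan finds tight blobs, flags noise, and silhouette matches brute force", {
  set.seed(30)
  ps <- pose_set(c(blob_poses(0.5, 10), blob_poses(3.0, 10)))
  cl <- cluster_dbscan(ps, seed = 1)
  expect_equal(length(unique(cl$labels[cl$labels > 0])), 2)
  expect_gt(cl$silhouette, 0.9)

  # brute-force silhouette on a 12-point instance
  X <- cl$reduced
  keep <- cl$labels > 0
  s_oracle <- mean(silhouette_oracle(X[keep, , drop = FALSE], cl$labels[keep]))
  expect_equal(cl$silhouette, s_oracle, tolerance = 1e-12)

  # uniform points at low density relative to eps: mostly noise
  set.seed(31)
  ps_u <- pose_set(lapply(1:24, function(i) matrix(runif(8, 0, 20), 2, 4)))
  cl_u <- cluster_dbscan(ps_u, eps = 2, seed = 1)
  expect_gte(mean(cl_u$labels == 0), 0.5)
  expect_true(cl_u$all_noise || any(cl_u$labels == 0))

  expect_error(cluster_dbscan(pose_set(blob_poses(1, 3))), "at least 4 poses")
})

test_that("dbscan labelling is order-independent up to permutation", {
  set.seed(33)
  base <- c(blob_poses(0.5, 8), blob_poses(2.5, 8))
  perm <- sample(16)
  cl_a <- cluster_dbscan(pose_set(base), seed = 1)
  cl_b <- cluster_dbscan(pose_set(base[perm]), seed = 1)
  # same co-membership structure
  co_a <- outer(cl_a$labels, cl_a$labels, `==`) & cl_a$labels > 0
  co_b <- outer(cl_b$labels, cl_b$labels, `==`) & cl_b$labels > 0
  expect_equal(co_a[perm, perm], co_b)
})

test_that("pose RMSD matches the brute-force double loop", {
  set.seed(40)
  ps <- pose_set(blob_poses(0.9, 5, n_atoms = 3, n_res = 4))
  out <- pose_rmsd(ps)
  # oracle
  Dbar <- Reduce(`+`, ps$D) / 5
  oracle <- vapply(1:5, function(q) {
    tot <- 0
    for (i in 1:3) tot <- tot + sum((ps$D[[q]][i, ] - Dbar[i, ])^2)
    sqrt(tot / 3)
  }, numeric(1))
  expect_equal(out$rmsd, oracle, tolerance = 1e-12)
  expect_gte(attr(out, "mean"), 0)

  # identical poses: all zero; two poses: symmetric about the mean
  same <- pose_rmsd(pose_set(rep(list(matrix(0.5, 2, 2)), 4)))
  expect_equal(same$rmsd, rep(0, 4))
  two <- pose_rmsd(pose_set(blob_poses(1, 2)))
  expect_equal(two$rmsd[1], two$rmsd[2], tolerance = 1e-12)
})

test_that("written poses round-trip with matching atom counts", {
  fx <- small_fixture(n_frames = 30, seed = 16, n_repeats = 1)
  m <- fx$models[[1]]
  sev <- site_events(m, 1:5, cp_default, site_id = 1L)
  poses <- score_poses(collect_poses(m, 1:5, sev))
  rp <- representative_pose(poses)
  path <- tempfile(fileext = ".gro")
  write_pose(rp, m, path)
  g <- read_gro(path)
  n_expected <- length(unlist(m$residues$atom_indices)) +
    length(m$ligands$atom_indices[[rp$molecule_id]])
  expect_equal(nrow(g$atoms), n_expected)
})
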