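cp_default <- cutoff_pair(0.475, 0.8)

test_that("network weights are clamped Pearson correlations of the feature vectors", {
  fx <- small_fixture(n_frames = 80, seed = 3, n_repeats = 1)
  suppressWarnings(
    net <- build_network(fx$models, cp_default, features = "distance")
  )
  m <- fx$models[[1]]
  dml <- lipidsite:::distance_matrix_list(m)
  # direct Pearson on two residues' concatenated distance vectors
  for (pair in list(c(1, 2), c(1, 12), c(11, 15))) {
    v1 <- as.numeric(t(dml[[as.character(pair[1])]]))
    v2 <- as.numeric(t(dml[[as.character(pair[2])]]))
    expect_equal(
      net$weights[pair[1], pair[2]],
      max(0, cor(v1, v2)),
      tolerance = 1e-12
    )
  }
  expect_true(isSymmetric(unname(net$weights)))
  expect_true(all(net$weights >= 0 & net$weights <= 1))
  expect_equal(unname(diag(net$weights)), rep(0, 30))

  # identical vectors give weight 1: trivially true of a residue with itself,
  # checked via duplicated geometry in the binary features
  suppressWarnings(netb <- build_network(fx$models, cp_default))
  expect_true(all(diag(netb$weights) == 0))
})

test_that("zero-variance features produce zero weights with a warning", {
  fx <- small_fixture(n_frames = 50, seed = 8, n_repeats = 1)
  expect_warning(
    net <- build_network(fx$models, cp_default),
    "zero variance"
  )
  # residues never contacted have no edges
  never <- 25 # far from both planted sites
  expect_equal(sum(net$weights[never, ]), 0)
})

test_that("modularity matches its definition on known partitions", {
  # two disconnected unit-weight 4-cliques
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  net <- residue_network(W)

  expect_equal(modularity_q(net, rep(1L, 8)), 0)
  expect_equal(modularity_q(net, rep(c(1L, 2L), each = 4)), 0.5)

  # singletons: Q = -sum (k_i/2m)^2
  expect_equal(
    modularity_q(net, 1:8),
    -sum((net$degrees / (2 * net$m))^2)
  )

  expect_error(
    modularity_q(residue_network(matrix(0, 3, 3)), rep(1, 3)),
    "no edges"
  )
})

test_that("the correct clique split is the exhaustive-enumeration optimum", {
  W <- matrix(0, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  net <- residue_network(W)
  best <- best_partition_oracle(net)
  expect_equal(best$q, 0.5)
  expect_equal(length(unique(best$membership[1:4])), 1)
  expect_equal(length(unique(best$membership[5:8])), 1)
})

test_that("louvain recovers planted structure and never lowers Q across passes", {
  # two disconnected triangles: exhaustive optimum
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  net <- residue_network(W)
  part <- louvain_partition(net, seed = 1)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(length(unique(part$membership[1:3])), 1)
  expect_equal(part$q, best_partition_oracle(net)$q)

  # complete uniform graph: no split improves Q
  Wc <- matrix(1, 6, 6)
  diag(Wc) <- 0
  pc <- louvain_partition(residue_network(Wc), seed = 2)
  expect_equal(length(unique(pc$membership)), 1)
  expect_equal(pc$q, 0)

  # planted 2-block graph
  set.seed(10)
  Wp <- matrix(0.05, 20, 20)
  Wp[1:10, 1:10] <- 1
  Wp[11:20, 11:20] <- 1
  diag(Wp) <- 0
  netp <- residue_network(Wp)
  pp <- louvain_partition(netp, seed = 3)
  expect_equal(length(unique(pp$membership)), 2)
  expect_equal(length(unique(pp$membership[1:10])), 1)
  planted_q <- modularity_q(netp, rep(1:2, each = 10))
  expect_gte(pp$q, planted_q - 1e-12)
  # Q never decreases over passes, and beats the all-in-one baseline
  expect_true(all(diff(pp$q_trace) >= -1e-12))
  expect_gte(pp$q, 0)
})

test_that("louvain agrees with an independent community-detection oracle", {
  skip_if_not_installed("igraph")
  set.seed(21)
  for (rep in 1:3) {
    n <- 12
    W <- matrix(runif(n * n, 0, 0.2), n, n)
    block <- sample(rep(1:2, each = n / 2))
    W[block == 1, block == 1] <- W[block == 1, block == 1] + 0.8
    W[block == 2, block == 2] <- W[block == 2, block == 2] + 0.8
    W <- (W + t(W)) / 2
    diag(W) <- 0
    net <- residue_network(W)
    part <- louvain_partition(net, seed = rep)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected", weighted = TRUE)
    ref <- igraph::cluster_louvain(g)
    expect_equal(
      modularity_q(net, part$membership),
      igraph::modularity(g, igraph::membership(ref), weights = igraph::E(g)$weight),
      tolerance = 0.02
    )
    # cross-check our Q computation itself on our own partition
    expect_equal(
      part$q,
      igraph::modularity(g, part$membership, weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("filter_sites drops small communities and keeps survivors disjoint", {
  part <- structure(
    list(membership = c(1, 1, 1, 1, 1, 1, 2, 2, 2, 3, 3, 3, 3, 3)),
    class = "partition"
  )
  sites <- filter_sites(part, nodes = 1:14, min_size = 4)
  expect_equal(nrow(sites), 2)
  expect_equal(sort(vapply(sites$residues, length, integer(1))), c(5, 6))
  expect_equal(length(intersect(sites$residues[[1]], sites$residues[[2]])), 0)

  all_kept <- filter_sites(part, nodes = 1:14, min_size = 1)
  expect_equal(nrow(all_kept), 3)

  expect_warning(
    none <- filter_sites(part, nodes = 1:14, min_size = 10),
    "no binding sites"
  )
  expect_equal(nrow(none), 0)
})

test_that("site events equal the dual-cutoff machine on the residue-minimum series", {
  fx <- small_fixture(n_frames = 120, seed = 12, n_repeats = 1)
  m <- fx$models[[1]]
  dml <- lipidsite:::distance_matrix_list(m)
  site_res <- 1:5
  sev <- site_events(m, site_res, cp_default, site_id = 1L)
  # oracle: detect_events applied to the elementwise minimum series
  for (li in seq_len(nrow(m$ligands))) {
    series <- do.call(pmin, lapply(site_res, function(r) dml[[as.character(r)]][li, ]))
    oracle <- hysteresis_oracle(series, 0.475, 0.8, dt = m$dt)
    got <- sev[sev$molecule_id == li, ]
    expect_equal(got$start_frame, oracle$start_frame)
    expect_equal(got$end_frame, oracle$end_frame)
  }
  # a molecule hopping within the site yields fewer site events than the sum
  # of its per-residue events
  ev_res <- detect_all_events(m, cp_default)
  per_res <- sum(ev_res$residue %in% site_res & ev_res$molecule_id == 1)
  expect_lte(nrow(sev[sev$molecule_id == 1, ]), max(per_res, 1))
})

test_that("Shrake-Rupley areas match the analytic sphere and sum over sites", {
  r <- 0.2
  probe <- 0.14
  a <- shrake_rupley(matrix(0, 1, 3), radii = r, probe_radius = probe, n_points = 960)
  expect_lt(abs(a - 4 * pi * (r + probe)^2) / (4 * pi * (r + probe)^2), 0.01)

  # far-separated atoms: total = sum of isolated areas
  xyz <- rbind(c(0, 0, 0), c(10, 0, 0))
  a2 <- shrake_rupley(xyz, radii = c(0.2, 0.17))
  expect_equal(a2[1], 4 * pi * 0.34^2, tolerance = 0.01)
  expect_equal(a2[2], 4 * pi * 0.31^2, tolerance = 0.01)

  # overlap strictly reduces area, monotonically with approach
  seps <- seq(0.66, 0.1, by = -0.08)
  tot <- vapply(seps, function(s) {
    sum(shrake_rupley(rbind(c(0, 0, 0), c(s, 0, 0)),
      radii = c(0.17, 0.17), n_points = 480
    ))
  }, numeric(1))
  expect_true(all(diff(tot) < 0))
})

test_that("site surface area is the sum of its residues' atom areas", {
  fx <- small_fixture(n_frames = 3, seed = 2, n_repeats = 1)
  m <- fx$models[[1]]
  site_res <- 1:5
  sa <- site_surface_area(m, site_res, n_points = 240)
  expect_equal(nrow(sa), 3)
  # independent recomputation: per-atom areas summed over the site atoms
  prot_atoms <- unlist(m$residues$atom_indices)
  radii <- lipidsite:::atom_radii(m$atoms$atom_name[prot_atoms])
  a <- shrake_rupley(m$coords[prot_atoms, , 1], radii, n_points = 240)
  site_atoms <- prot_atoms %in% unlist(m$residues$atom_indices[site_res])
  per_res <- tapply(
    a[site_atoms],
    rep(site_res, lengths(m$residues$atom_indices[site_res])), sum
  )
  expect_equal(sa$area[1], sum(per_res), tolerance = 1e-12)
})
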