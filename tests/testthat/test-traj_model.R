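test_that("GRO round trip preserves atoms, coordinates, box and times", {
  atoms <- tibble::tibble(
    resid = c(1L, 1L, 2L), resname = c("ALA", "ALA", "LIG"),
    atom_name = c("BB", "SC1", "L1")
  )
  coords <- array(round(runif(3 * 3 * 4, 0, 5), 3), dim = c(3, 3, 4))
  path <- tempfile(fileext = ".gro")
  write_gro(atoms, coords, c(5, 5, 5), path, times = (0:3) * 100)
  g <- read_gro(path)
  expect_equal(dim(g$coords), c(3, 3, 4))
  expect_equal(g$coords, coords, tolerance = 1e-8)
  expect_equal(g$atoms$resname, atoms$resname)
  expect_equal(g$atoms$atom_name, atoms$atom_name)
  expect_equal(g$box[2, ], c(5, 5, 5))
  expect_equal(g$times, (0:3) * 100)
})

test_that("load_system resolves ligand copies, contact atoms and dt", {
  fx <- small_fixture(n_frames = 5, n_ligands = 2, n_repeats = 1)
  m <- fx$models[[1]]
  expect_s3_class(m, "system_model")
  expect_equal(m$n_frames, 5)
  expect_equal(nrow(m$ligands), 2)
  expect_equal(m$dt, 0.5) # inferred from frame time stamps (ps -> ns)

  # restricting ligand contact atoms to one name
  m1 <- load_system(fx$paths$trajectories, fx$paths$topology, "LIG",
    ligand_atom_selection = "name L1"
  )[[1]]
  expect_equal(lengths(m1$ligands$contact_atom_indices), rep(1L, 2))
  expect_true(all(unlist(m1$ligands$contact_atom_indices) %in%
    unlist(m1$ligands$atom_indices)))

  expect_error(
    load_system(fx$paths$trajectories, fx$paths$topology, "NOPE"),
    "ligand not found"
  )
})

test_that("min_distance_series equals the exhaustive pairwise minimum", {
  res_xyz <- matrix(c(0, 0, 0, 0.3, 0, 0, 0, 0.4, 0), 3, 3, byrow = TRUE)
  lig_xyz <- matrix(c(1, 1, 1, 0.5, 0.1, 0), 2, 3, byrow = TRUE)
  m <- toy_system(list(res_xyz), list(lig_xyz))
  d <- min_distance_series(m, 1, 1)$distance
  brute <- min(apply(res_xyz, 1, function(a) {
    apply(lig_xyz, 1, function(b) sqrt(sum((a - b)^2)))
  }))
  expect_equal(d, brute)

  # coincident atoms give zero
  m0 <- toy_system(list(res_xyz), list(res_xyz[1, , drop = FALSE]))
  expect_equal(min_distance_series(m0, 1, 1)$distance, 0)
})

test_that("minimum-image convention wraps distances across the box", {
  m <- toy_system(
    list(matrix(c(0.1, 0, 0), 1, 3)),
    list(matrix(c(3.9, 0, 0), 1, 3)),
    box = c(4, 4, 4)
  )
  expect_equal(min_distance_series(m, 1, 1)$distance, 0.2, tolerance = 1e-10)
})

test_that("distances are symmetric, translation-invariant, and grow under atom subsetting", {
  set.seed(31)
  res_xyz <- matrix(runif(9, 0, 3), 3, 3)
  lig_xyz <- matrix(runif(6, 0, 3), 2, 3)
  m <- toy_system(list(res_xyz), list(lig_xyz), box = c(6, 6, 6))

  # symmetry: swap which set is residue and which is ligand
  m_swap <- toy_system(list(lig_xyz), list(res_xyz), box = c(6, 6, 6))
  expect_equal(
    min_distance_series(m, 1, 1)$distance,
    min_distance_series(m_swap, 1, 1)$distance
  )

  # rigid translation modulo the box leaves distances unchanged
  shift <- c(2.2, -1.3, 0.7)
  m_shift <- toy_system(
    list(sweep(res_xyz, 2, shift, `+`)),
    list(sweep(lig_xyz, 2, shift, `+`)),
    box = c(6, 6, 6)
  )
  expect_equal(
    min_distance_series(m, 1, 1)$distance,
    min_distance_series(m_shift, 1, 1)$distance,
    tolerance = 1e-10
  )

  # dropping contact atoms can only increase the minimum
  m_sub <- m
  m_sub$ligands$contact_atom_indices[[1]] <-
    m$ligands$contact_atom_indices[[1]][1]
  expect_gte(
    min_distance_series(m_sub, 1, 1)$distance,
    min_distance_series(m, 1, 1)$distance
  )
})

test_that("selection grammar handles resname, name, resid ranges and errors", {
  atoms <- tibble::tibble(
    atom_index = 1:6, resid = c(1L, 1L, 2L, 3L, 4L, 4L),
    resname = c("ALA", "ALA", "GLY", "ALA", "LIG", "LIG"),
    atom_name = c("BB", "SC1", "BB", "BB", "L1", "L2")
  )
  expect_equal(lipidsite:::parse_selection("resname GLY", atoms), atoms$resname == "GLY")
  expect_equal(lipidsite:::parse_selection("name BB SC1", atoms), atoms$atom_name %in% c("BB", "SC1"))
  expect_equal(lipidsite:::parse_selection("resid 2-3", atoms), atoms$resid %in% 2:3)
  expect_true(all(lipidsite:::parse_selection("all", atoms)))
  expect_error(lipidsite:::parse_selection("chain A", atoms), "unknown selection keyword")
})
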