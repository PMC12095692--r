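# small deterministic trajectory helpers ------------------------------------

# a frame with the ligand placed at an exact offset from one protein atom
two_body_traj <- function(gap) {
  atoms <- tibble::tibble(
    chain = c("A", "A", "A", "L"),
    resid = c(1, 2, 3, 1),
    resname = c("ALA", "ALA", "ALA", "LIG"),
    name = c("CA", "CA", "CA", "C1"),
    element = "C",
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  coords <- array(0, c(1, 4, 3))
  coords[1, 2, ] <- c(0, 5, 0)
  coords[1, 3, ] <- c(0, 10, 0)
  coords[1, 4, ] <- c(gap, 0, 0)
  lf_trajectory(atoms, coords)
}

test_that("the contact cutoff is a strict inequality at 4 Angstrom", {
  expect_equal(contact_fingerprint(two_body_traj(3.99), 1), "A:1")
  expect_equal(contact_fingerprint(two_body_traj(4.00), 1), character())
  expect_equal(contact_fingerprint(two_body_traj(50), 1), character())
})

test_that("fingerprints equal the brute-force all-pairs oracle", {
  traj <- gen_trajectory(n_frames = 30, seed = 8)
  fps <- contact_fingerprints(traj)
  for (f in seq_len(30)) {
    expect_identical(fps[[as.character(f)]],
                     brute_force_contacts(traj, f))
  }
})

test_that("hydrogens are excluded from the contact criterion", {
  traj <- two_body_traj(3.0)
  traj$atoms$element[4] <- "H" # the only ligand atom is now a hydrogen
  expect_error(contact_fingerprints(traj), "heavy atoms")
})

test_that("bound-frame filtering applies the >= 5 residue rule exactly", {
  traj <- gen_trajectory(n_frames = 100,
                         epitope_specs = list(
                           list(residues = paste0("A:", 5:10),
                                fraction = 0.3)),
                         seed = 2)
  fps <- contact_fingerprints(traj)
  bound <- filter_bound_frames(traj, fps = fps, min_residues = 5)
  man <- attr(traj, "manifest")
  expect_setequal(bound, man$epitopes[[1]]$frames)
  # raising the bar to more residues than planted empties the list
  expect_length(filter_bound_frames(traj, fps = fps, min_residues = 20), 0)
  # boundary: a frame contacting exactly 5 residues is retained at 5 and
  # dropped at 6 only if it has no 6th contact
  n5 <- lengths(fps[as.character(bound)])
  expect_true(all(n5 >= 5))
})

test_that("an all-unbound trajectory yields no bound frames", {
  traj <- gen_trajectory(n_frames = 50,
                         epitope_specs = list(
                           list(residues = paste0("A:", 5:10),
                                fraction = 0)),
                         seed = 3)
  expect_length(filter_bound_frames(traj), 0)
  rep <- detect_epitopes(traj)
  expect_equal(nrow(rep), 0)
})

test_that("a fixed ligand atom accumulates into a single voxel", {
  atoms <- tibble::tibble(
    chain = c("A", "A", "A", "L"),
    resid = c(1, 2, 3, 1),
    resname = c("ALA", "ALA", "ALA", "LIG"),
    name = c("CA", "CA", "CA", "C1"),
    element = "C",
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  coords <- array(0, c(10, 4, 3))
  for (f in 1:10) {
    coords[f, 2, ] <- c(3, 1, 0)
    coords[f, 3, ] <- c(1, 4, 2)
    coords[f, 4, ] <- c(2.2, 2.2, 2.2)
  }
  traj <- lf_trajectory(atoms, coords)
  grid <- density_grid(traj, bound_frames = 1:10, spacing = 1)
  expect_equal(nrow(grid), 1)
  expect_equal(grid$count, 10)
  expect_equal(attr(grid, "total"), 10)
})

test_that("density totals are conserved and identity symmetry is neutral", {
  traj <- gen_trajectory(n_frames = 60, seed = 5)
  fps <- contact_fingerprints(traj)
  bound <- filter_bound_frames(traj, fps = fps)
  g0 <- density_grid(traj, bound)
  n_lig <- sum(traj$atoms$is_ligand)
  expect_equal(attr(g0, "total"), length(bound) * n_lig)
  g_id <- density_grid(traj, bound,
                       symmetry_ops = list(rigid_transform()))
  expect_equal(as.data.frame(g_id), as.data.frame(g0))
  # 2-fold folding conserves the total count
  c2 <- rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  g_fold <- density_grid(traj, bound, symmetry_ops = list(c2))
  expect_equal(attr(g_fold, "total"), attr(g0, "total"))
})

test_that("2-fold folding maps both symmetric half-densities together", {
  # one ligand atom alternating between a position and its C2 image
  atoms <- tibble::tibble(
    chain = c("A", "A", "A", "L"),
    resid = c(1, 2, 3, 1),
    resname = c("ALA", "ALA", "ALA", "LIG"),
    name = c("CA", "CA", "CA", "C1"),
    element = "C",
    is_ligand = c(FALSE, FALSE, FALSE, TRUE))
  coords <- array(0, c(8, 4, 3))
  pos <- c(5.2, 3.2, 1.2)
  img <- c(-5.2, -3.2, 1.2)
  for (f in 1:8) {
    coords[f, 2, ] <- c(3, 1, 0)
    coords[f, 3, ] <- c(1, 4, 2)
    coords[f, 4, ] <- if (f %% 2 == 0) pos else img
  }
  traj <- lf_trajectory(atoms, coords)
  c2 <- rigid_transform(diag(c(-1, -1, 1)), c(0, 0, 0))
  g <- density_grid(traj, 1:8, symmetry_ops = list(c2))
  # all 8 counts land in one voxel (the canonical image)
  expect_equal(nrow(g), 1)
  expect_equal(g$count, 8)
})

test_that("clustering separates disjoint planted residue sets", {
  fps <- c(
    stats::setNames(rep(list(paste0("A:", 1:6)), 5), 1:5),
    stats::setNames(rep(list(paste0("B:", 11:16)), 3), 6:8))
  cl <- cluster_fingerprints(fps)
  expect_equal(dplyr::n_distinct(cl$cluster), 2)
  expect_equal(dplyr::n_distinct(cl$cluster[cl$frame <= 5]), 1)
  expect_equal(dplyr::n_distinct(cl$cluster[cl$frame > 5]), 1)
  # identical fingerprints collapse to one cluster
  cl1 <- cluster_fingerprints(stats::setNames(
    rep(list(paste0("A:", 1:6)), 4), 1:4))
  expect_equal(unique(cl1$cluster), 1L)
})

test_that("chain canonicalization merges symmetry-equivalent epitopes", {
  fps <- c(
    stats::setNames(rep(list(paste0("A:", 1:6)), 4), 1:4),
    stats::setNames(rep(list(paste0("C:", 1:6)), 4), 5:8))
  # without a chain map: two clusters; with C -> A: one
  expect_equal(dplyr::n_distinct(cluster_fingerprints(fps)$cluster), 2)
  expect_equal(dplyr::n_distinct(
    cluster_fingerprints(fps, chain_map = c(C = "A"))$cluster), 1)
})

test_that("noisy planted epitopes are recovered by the cluster step", {
  set.seed(11)
  base1 <- paste0("A:", 1:8)
  base2 <- paste0("B:", 11:18)
  all_res <- c(paste0("A:", 1:20), paste0("B:", 1:20))
  noisy <- function(base) {
    keep <- base[stats::runif(length(base)) > 0.05]
    extra <- sample(setdiff(all_res, base),
                    stats::rbinom(1, 2, 0.4))
    sort(unique(c(keep, extra)))
  }
  truth <- rep(1:2, c(60, 40))
  fps <- stats::setNames(
    lapply(truth, function(k) noisy(if (k == 1) base1 else base2)),
    seq_along(truth))
  cl <- cluster_fingerprints(fps)
  # majority label per planted epitope
  tab <- table(truth, cl$cluster)
  recovered <- sum(apply(tab, 1, max)) / length(truth)
  expect_gte(recovered, 0.9)
})

test_that("occupancies use all frames and sort clusters by population", {
  traj <- gen_trajectory(n_frames = 1000, seed = 1)
  rep <- detect_epitopes(traj)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$occupancy_pct, c(13.2, 10.1))
  expect_equal(rep$n_frames, c(132, 101))
  expect_equal(sum(rep$n_frames) / attr(rep, "total_frames") * 100,
               sum(rep$occupancy_pct))
  # each bound frame is in exactly one cluster
  expect_equal(anyDuplicated(unlist(rep$frames)), 0)
})

test_that("hot-spot residues are flagged in the per-residue table", {
  traj <- gen_trajectory(n_frames = 100, seed = 4)
  rep <- detect_epitopes(traj, hot_spots = c("A:5", "A:6"))
  res1 <- rep$residues[[1]]
  expect_true(any(res1$hot_spot))
  expect_setequal(res1$residue[res1$hot_spot],
                  intersect(res1$residue, c("A:5", "A:6")))
})

test_that("occupancies are invariant to frame reordering", {
  traj <- gen_trajectory(n_frames = 120, seed = 6)
  set.seed(2)
  perm <- sample(120)
  traj2 <- traj
  traj2$coords <- traj$coords[perm, , , drop = FALSE]
  r1 <- detect_epitopes(traj)
  r2 <- detect_epitopes(traj2)
  expect_equal(sort(r1$occupancy_pct), sort(r2$occupancy_pct))
})

test_that("multi-model PDB round-trips through write and read", {
  traj <- gen_trajectory(n_frames = 5, seed = 9)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, path)
  back <- read_trajectory_pdb(path, ligand_resname = "LIG")
  expect_equal(n_frames(back), 5)
  expect_equal(sum(back$atoms$is_ligand), sum(traj$atoms$is_ligand))
  expect_equal(back$coords, traj$coords, tolerance = 1e-3)
  # epitope detection gives identical occupancies on the file copy
  expect_equal(detect_epitopes(back)$occupancy_pct,
               detect_epitopes(traj)$occupancy_pct)
})

test_that("the density grid writes a parseable OpenDX file", {
  traj <- gen_trajectory(n_frames = 40, seed = 10)
  bound <- filter_bound_frames(traj)
  g <- density_grid(traj, bound)
  path <- withr::local_tempfile(fileext = ".dx")
  write_dx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], "gridpositions")
  counts <- as.integer(strsplit(sub(".*counts ", "", lines[1]), " ")[[1]])
  expect_equal(prod(counts > 0), 1)
  data_start <- grep("data follows", lines) + 1
  vals <- as.numeric(unlist(strsplit(
    lines[data_start:(length(lines) - 1)], " ")))
  expect_equal(sum(vals), attr(g, "total"))
})
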