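test_that("PDB round trip: single and multi-MODEL files, atom table shared", {
  toy <- gen_toy_frames(n_clusters = 2, frames_per_cluster = 2,
                        jitter_sd = 0.05, center_separation = 5, seed = 5)
  single <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, single, frames = 1)
  fs1 <- read_frames(single, ligand_resname = "LIG")
  expect_equal(n_frames(fs1), 1)
  expect_equal(sum(fs1$atoms$is_ligand), sum(toy$frames$atoms$is_ligand))
  # coordinates survive to PDB precision (3 decimals)
  expect_equal(fs1$frames[[1]], toy$frames$frames[[1]], tolerance = 1e-3)

  multi <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, multi)
  fs4 <- read_frames(multi, ligand_resname = "LIG")
  expect_equal(n_frames(fs4), 4)
  expect_equal(fs4$atoms, fs1$atoms)

  expect_error(read_frames(single, ligand_resname = "XYZ"), "ligand")
})

test_that("mismatched atom counts across files are rejected", {
  toy <- gen_toy_frames(n_clusters = 1, frames_per_cluster = 1, seed = 6)
  a <- withr::local_tempfile(fileext = ".pdb")
  write_frames(toy$frames, a)
  # drop one atom
  small <- toy$frames
  small$atoms <- small$atoms[-1, ]
  small$atoms$atom_id <- seq_len(nrow(small$atoms))
  small$frames <- list(toy$frames$frames[[1]][-1, ])
  fs_small <- frame_set(small$atoms, small$frames)
  b <- withr::local_tempfile(fileext = ".pdb")
  write_frames(fs_small, b)
  expect_error(read_frames(c(a, b), ligand_resname = "LIG"),
               "atom count mismatch")
})

test_that("binding-site selection uses <= cutoff on heavy atoms only", {
  atoms <- data.frame(
    atom_id = 1:5,
    name = c("C1", "CA", "CB", "CC", "HA"),
    element = c("C", "C", "C", "C", "H"),
    resno = c(900L, 1L, 2L, 3L, 1L),
    resname = c("LIG", rep("ALA", 4)),
    chain = "A",
    is_ligand = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  co <- rbind(c(0, 0, 0), c(3, 0, 0), c(4.9, 0, 0), c(5.1, 0, 0), c(2, 0, 0))
  fs <- frame_set(atoms, list(co))
  site <- select_binding_site(fs, cutoff = 5)
  expect_equal(site$atom_indices, c(2L, 3L))  # 5.1 A out; hydrogen excluded
  expect_error(select_binding_site(fs, cutoff = 0.1), "empty binding site")
})

test_that("rmsd has translation/rigid-motion semantics and pseudometric properties", {
  set.seed(31)
  f1 <- matrix(stats::rnorm(30), 10, 3)
  expect_equal(rmsd_frames(f1, f1, 1:10), 0)
  f2 <- sweep(f1, 2, c(3, 4, 0), "+")
  expect_equal(rmsd_frames(f1, f2, 1:10, superpose = FALSE), 5)
  # arbitrary rigid motion is removed by superposition
  th <- 0.7
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  f3 <- sweep(f1 %*% Rz, 2, c(1, -2, 5), "+")
  expect_equal(rmsd_frames(f1, f3, 1:10, superpose = TRUE), 0, tolerance = 1e-6)
  expect_error(rmsd_frames(f1, f2, integer(0)), "empty")

  # symmetry, triangle inequality, superposed <= raw (random frames)
  for (rep in 1:10) {
    a <- matrix(stats::rnorm(30), 10, 3)
    b <- matrix(stats::rnorm(30), 10, 3)
    c_ <- matrix(stats::rnorm(30), 10, 3)
    dab <- rmsd_frames(a, b, 1:10)
    expect_equal(dab, rmsd_frames(b, a, 1:10), tolerance = 1e-9)
    expect_lte(dab, rmsd_frames(a, c_, 1:10) + rmsd_frames(c_, b, 1:10) + 1e-9)
    expect_lte(rmsd_frames(a, b, 1:10, superpose = TRUE), dab + 1e-9)
  }
})

test_that("pairwise RMSD matrix is symmetric, zero-diagonal and element-exact", {
  toy <- gen_toy_frames(n_clusters = 2, frames_per_cluster = 3,
                        jitter_sd = 0.2, center_separation = 6, seed = 32)
  site <- select_binding_site(toy$frames, cutoff = 5)
  D <- pairwise_rmsd_matrix(toy$frames, site)
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 6))
  expect_equal(D[2, 5],
               rmsd_frames(toy$frames$frames[[2]], toy$frames$frames[[5]],
                           site$atom_indices, superpose = TRUE))
})

test_that("affinity propagation recovers planted clusters and trivial cases", {
  expect_equal(affinity_propagation(matrix(0, 1, 1))$exemplars, 1L)

  toy <- gen_toy_frames(n_clusters = 3, frames_per_cluster = 10,
                        jitter_sd = 0.1, center_separation = 10, seed = 33)
  site <- select_binding_site(toy$frames, cutoff = 5)
  D <- pairwise_rmsd_matrix(toy$frames, site)
  ap <- affinity_propagation(D)
  expect_length(ap$exemplars, 3)
  expect_true(same_partition(ap$labels, toy$labels))
  expect_equal(sum(ap$populations), 30)
  # exemplars belong to their own clusters
  expect_equal(ap$labels[ap$exemplars], seq_along(ap$exemplars))

  expect_error(affinity_propagation(matrix(1, 2, 3)), "square")
  expect_error(affinity_propagation(D, damping = 0.3), "damping")
})

test_that("non-convergence raises an error carrying partial state", {
  set.seed(34)
  X <- matrix(stats::runif(20), 10, 2)
  D <- as.matrix(stats::dist(X))
  err <- tryCatch(affinity_propagation(D, max_iter = 3),
                  error = function(e) e)
  expect_s3_class(err, "ensdock_ap_no_convergence")
  expect_true(is.matrix(err$partial$R))
  expect_equal(err$partial$n_iter, 3L)
})

test_that("exemplar count is monotone non-decreasing in the preference", {
  toy <- gen_toy_frames(n_clusters = 3, frames_per_cluster = 8,
                        jitter_sd = 0.3, center_separation = 8, seed = 35)
  site <- select_binding_site(toy$frames, cutoff = 5)
  D <- pairwise_rmsd_matrix(toy$frames, site)
  prefs <- c(-500, -200, -50, -10, -1)
  ks <- vapply(prefs, function(p)
    length(affinity_propagation(D, preference = p)$exemplars), integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("representatives returns exemplars of the most populated clusters", {
  asg <- structure(list(exemplars = c(4L, 9L, 17L, 23L),
                        labels = rep(1:4, c(5, 30, 15, 50)),
                        populations = c(5L, 30L, 15L, 50L)),
                   class = "cluster_assignment")
  expect_equal(representatives(asg, 3), c(23L, 9L, 17L))
  # population tie -> lower cluster index first
  tie <- structure(list(exemplars = c(2L, 7L), labels = rep(1:2, c(4, 4)),
                        populations = c(4L, 4L)),
                   class = "cluster_assignment")
  expect_equal(representatives(tie, 1), 2L)
  one <- structure(list(exemplars = 3L, labels = rep(1L, 6),
                        populations = 6L),
                   class = "cluster_assignment")
  expect_warning(r <- representatives(one, 3), "only 1")
  expect_equal(r, 3L)
})

test_that("structure clustering by binding-site similarity finds family medoids", {
  set.seed(36)
  # two planted conformational families of 4 single-frame structures each
  toyA <- gen_toy_frames(n_clusters = 2, frames_per_cluster = 4,
                         jitter_sd = 0.15, center_separation = 7, seed = 36)
  structs <- lapply(seq_len(8), function(i)
    frame_set(toyA$frames$atoms, toyA$frames$frames[i]))
  names(structs) <- sprintf("S%d", 1:8)
  med <- cluster_structures_by_site(structs, n_clusters = 2)
  expect_length(med, 2)
  fam <- toyA$labels[match(med, names(structs))]
  expect_setequal(fam, c(1, 2))  # one medoid per family

  # n_clusters = n_structures: every structure its own medoid
  expect_setequal(cluster_structures_by_site(structs, n_clusters = 8),
                  names(structs))

  # all-identical structures: zero distances, first ids by convention
  same <- lapply(1:4, function(i)
    frame_set(toyA$frames$atoms, toyA$frames$frames[1]))
  names(same) <- sprintf("T%d", 1:4)
  expect_length(cluster_structures_by_site(same, n_clusters = 2), 2)
})

test_that("pocket volume recovers analytic cavities and empties", {
  cube <- make_protein_frame(cube_shell(half = 6.1))
  site <- binding_site_spec(seq_len(nrow(cube$atoms)))
  v_cube <- pocket_volume(cube, site)
  expect_equal(v_cube, 216, tolerance = 0.1)  # 6 A cube
  # grid-convergence: halving the spacing moves the estimate < 10%
  v_fine <- pocket_volume(cube, site, grid_spacing = 0.25)
  expect_lt(abs(v_cube - v_fine) / v_fine, 0.1)

  sph <- make_protein_frame(sphere_shell(1000, r = 7.1))
  v_sph <- pocket_volume(sph, binding_site_spec(seq_len(1000)))
  expect_equal(v_sph, 4 / 3 * pi * 4^3, tolerance = 0.1)

  # solid block of atoms: no cavity
  g <- seq(-3, 3, by = 1)
  blk <- make_protein_frame(as.matrix(expand.grid(g, g, g)))
  expect_equal(pocket_volume(blk, binding_site_spec(seq_len(nrow(blk$atoms)))), 0)

  # cavity open to the boundary is solvent, not pocket
  co <- cube_shell(half = 6.1)
  open_face <- co[!(abs(co[, 1] - 6.1) < 1e-9), , drop = FALSE]
  vo <- pocket_volume(make_protein_frame(open_face),
                      binding_site_spec(seq_len(nrow(open_face))))
  expect_equal(vo, 0)
})
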