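test_that("rmsd vanishes under the allowed transform group", {
  s <- generate_structure(30, "random_walk", seed = 1)
  expect_equal(rmsd(s, s), 0, tolerance = 1e-12)
  for (sd in 1:3) {
    moved <- random_rigid_motion(s, seed = sd)
    expect_lt(rmsd(s, moved, allow_reflection = FALSE), 1e-8)
  }
  mirrored <- structure3d(s$coords %*% diag(c(-1, 1, 1)))
  expect_lt(rmsd(s, mirrored, allow_reflection = TRUE), 1e-8)
})

test_that("chirality is detected when reflection is disallowed", {
  s <- generate_structure(25, "helix")  # a helix is chiral
  mirrored <- structure3d(s$coords %*% diag(c(-1, 1, 1)))
  r_strict <- rmsd(s, mirrored, allow_reflection = FALSE)
  expect_gt(r_strict, 0.1)
  # agree with a brute-force rotation-search oracle
  oracle <- rigid_rmsd_oracle(s$coords, mirrored$coords)
  expect_equal(r_strict, oracle, tolerance = 1e-4)
})

test_that("rmsd is symmetric without scaling and averaged with scaling", {
  a <- generate_structure(20, "random_walk", seed = 2)
  b <- generate_structure(20, "random_walk", seed = 3)
  expect_equal(rmsd(a, b), rmsd(b, a), tolerance = 1e-10)
  scaled <- structure3d(a$coords * 3)
  expect_lt(rmsd(a, scaled, allow_scaling = TRUE), 1e-8)
  expect_gt(rmsd(a, scaled, allow_scaling = FALSE), 0.1)
})

test_that("rmsd only uses beads valid in both structures", {
  a <- generate_structure(10, "helix")
  b <- structure3d(a$coords, valid = c(FALSE, rep(TRUE, 9)))
  expect_equal(rmsd(a, b), 0, tolerance = 1e-12)
  c2 <- structure3d(a$coords, valid = c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_error(rmsd(a, c2), "at least 3")
})

test_that("distance Spearman is scale-free and near zero under the null", {
  a <- generate_structure(40, "random_walk", seed = 4)
  expect_equal(distance_spearman(a, a), 1)
  # power-of-two scaling keeps distances exactly proportional in floating
  # point, so the ranks are untouched
  expect_equal(distance_spearman(a, structure3d(a$coords * 2)), 1)
  # unrelated point clouds: correlation concentrates near zero
  null_rho <- sapply(1:20, function(sd) {
    set.seed(300 + sd)
    x <- structure3d(matrix(rnorm(300), 100, 3))
    y <- structure3d(matrix(rnorm(300), 100, 3))
    distance_spearman(x, y)
  })
  expect_lt(median(abs(null_rho)), 0.3)
  # two independent chains still correlate positively: both distance
  # matrices grow with genomic separation along the shared backbone
  walk_rho <- sapply(1:10, function(sd) {
    distance_spearman(generate_structure(100, "random_walk", seed = 100 + sd),
                      generate_structure(100, "random_walk", seed = 200 + sd))
  })
  expect_gt(median(walk_rho), 0.2)
})

test_that("rescaling matches its quantile semantics", {
  set.seed(5)
  u <- matrix(rnorm(300), 100, 3)
  sphere <- structure3d(u / sqrt(rowSums(u^2)))  # unit sphere shell
  r1 <- rescale_structure(sphere, diameter = 100, quantile = 1)
  expect_equal(max(sqrt(rowSums(r1$coords^2))), 50, tolerance = 1e-9)

  # an already-conforming structure is unchanged beyond centering
  r2 <- rescale_structure(r1, diameter = 100, quantile = 1)
  expect_equal(r2$coords, r1$coords, tolerance = 1e-9)

  # with quantile 0.99 a far outlier stays outside the sphere
  pts <- rbind(matrix(rnorm(297, sd = 1), 99, 3), c(50, 0, 0))
  r3 <- rescale_structure(structure3d(pts), diameter = 10, quantile = 0.99)
  expect_gt(sqrt(sum(r3$coords[100, ]^2)), 5)
  expect_error(rescale_structure(structure3d(matrix(0, 5, 3)), 10, 1),
               "coincident")
})

test_that("coarsening averages groups and commutes with rigid motion", {
  s <- generate_structure(20, "helix")
  expect_identical(coarsen_structure(s, 1), s)

  two <- structure3d(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(coarsen_structure(two, 2)$coords[1, ],
               c(x = 1, y = 0, z = 0))

  # invalid bead in a group: average over the valid ones only
  three <- structure3d(rbind(c(0, 0, 0), c(2, 0, 0), c(9, 9, 9)),
                       valid = c(TRUE, FALSE, TRUE))
  cs <- coarsen_structure(three, 2)
  expect_equal(unname(cs$coords[1, ]), c(0, 0, 0))
  expect_equal(unname(cs$coords[2, ]), c(9, 9, 9))  # trailing partial group

  set.seed(7)
  g <- structure3d(matrix(rnorm(12), 4, 3), chrom = rep("chr1", 4))
  moved <- random_rigid_motion(g, seed = 6)
  left <- coarsen_structure(moved, 2)$coords
  right <- random_rigid_motion(coarsen_structure(g, 2), seed = 6)$coords
  expect_equal(left, right, tolerance = 1e-10)

  # groups are anchored at each chromosome start
  s2 <- generate_structure(10, "helix")
  s2$chrom <- rep(c("chr1", "chr2"), each = 5)
  s2$bin_index <- rep(0:4, 2)
  cs2 <- coarsen_structure(s2, 2)
  expect_equal(cs2$chrom, rep(c("chr1", "chr2"), each = 3))
  expect_equal(cs2$bin_index, rep(0:2, 2))
})

test_that("binomial downsampling thins counts as expected", {
  m <- contact_matrix(random_count_matrix(20, seed = 8, lambda = 30))
  expect_identical(downsample_counts(m, 1, seed = 1)$counts, m$counts)
  expect_identical(sum(downsample_counts(m, 0, seed = 1)$counts), 0)

  total <- sum(m$counts[upper.tri(m$counts)])
  halves <- sapply(1:200, function(sd) {
    sum(downsample_counts(m, 0.5, seed = sd)$counts) / 2
  })
  expect_lt(abs(mean(halves) - 0.5 * total), 3 * sqrt(total * 0.25 / 200))
  expect_error(downsample_counts(m, 1.5), "fraction")

  # thinning composes: f1 then f2 matches f1*f2 in mean and variance
  two_step <- sapply(1:200, function(sd) {
    sum(downsample_counts(downsample_counts(m, 0.6, seed = sd), 0.5,
                          seed = 1000 + sd)$counts) / 2
  })
  one_step <- sapply(1:200, function(sd) {
    sum(downsample_counts(m, 0.3, seed = 2000 + sd)$counts) / 2
  })
  expect_equal(mean(two_step), mean(one_step),
               tolerance = 4 * sd(one_step) / sqrt(200) / mean(one_step))
  expect_lt(abs(var(two_step) / var(one_step) - 1), 0.5)
})

test_that("beads with no contacts in either replicate are masked in both", {
  inst <- helix_instance(n = 12, seed = 9)
  ma <- inst$counts
  matb <- ma$counts
  matb[4, ] <- 0L; matb[, 4] <- 0L
  mb <- contact_matrix(matb)
  a <- generate_structure(12, "helix")
  b <- generate_structure(12, "random_walk", seed = 2)
  fb <- filter_common_beads(a, b, ma, mb)
  expect_false(fb$a$valid[4])
  expect_false(fb$b$valid[4])
  expect_true(all(fb$a$valid[-4]))

  fb2 <- filter_common_beads(a, b, ma, ma)
  expect_identical(fb2$a$valid, a$valid)

  zero <- contact_matrix(matrix(0L, 12, 12) + 0L)
  expect_error(filter_common_beads(a, b, zero, mb), "no informative|no surviving")
})

test_that("the replicate comparison protocol returns sane summaries", {
  inst <- helix_instance(n = 30, seed = 11)
  m2 <- simulate_counts(inst$truth,
                        cfg = simulation_config(30, "helix", seed = 99))
  res <- compare_structures(inst$truth,
                            random_rigid_motion(inst$truth, seed = 3),
                            inst$counts, m2)
  expect_lt(res$rmsd, 1e-6)
  # rescaling perturbs near-tied distances at machine precision, so the
  # rank correlation is only numerically 1
  expect_gt(res$spearman, 0.99)
  expect_lte(res$n_common, 30)
})
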