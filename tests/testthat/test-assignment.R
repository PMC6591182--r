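test_that("world-to-voxel mapping rounds half away from zero and flags OOB", {
  expect_equal(world_to_voxel(c(0, 0, 0), diag(4)), cbind(0L, 0L, 0L))
  # 2.6 mm at 2 mm voxels: continuous index 1.3 -> voxel 1
  aff2 <- diag(c(2, 2, 2, 1))
  expect_equal(world_to_voxel(c(2.6, 0, 0), aff2), cbind(1L, 0L, 0L))
  # continuous index exactly x.5 rounds up (away from zero)
  expect_equal(world_to_voxel(c(3, 0, 0), aff2), cbind(2L, 0L, 0L))
  # out of bounds: marker row, no error
  idx <- world_to_voxel(rbind(c(50, 0, 0), c(2, 2, 2)), diag(4), c(10, 10, 10))
  expect_true(all(is.na(idx[1, ])))
  expect_equal(idx[2, ], c(2L, 2L, 2L))
  expect_error(world_to_voxel(c(0, 0, 0), matrix(0, 4, 4)), "singular")
})

test_that("traversed label sets match a fine-sampling oracle", {
  set.seed(55)
  arr <- array(0L, c(20, 20, 20))
  arr[2:5, 2:5, 2:5] <- 3L
  arr[15:18, 15:18, 15:18] <- 7L
  arr[8:12, 9:11, 9:11] <- 2L                  # corridor blob
  vol <- label_volume(arr, diag(c(1.2, 1.2, 1.2, 1)))
  sl <- rbind(c(3, 3, 3), c(12, 12, 12), c(20, 20, 20)) * 1.2
  expect_identical(streamline_labels(sl, vol), bf_streamline_labels(sl, vol))
  expect_true(all(c(3L, 7L) %in% streamline_labels(sl, vol)))

  # background-only streamline
  expect_identical(streamline_labels(rbind(c(0, 14, 2), c(5, 14, 2)) * 1.2, vol),
                   integer(0))
})

test_that("densification never skips a one-voxel wall between vertices", {
  arr <- array(0L, c(20, 20, 20))
  arr[, 10, ] <- 4L                            # 1-voxel-thick wall
  vol <- label_volume(arr, diag(4))
  sl <- rbind(c(5, 4, 5), c(5, 16, 5))         # vertex spacing 12 voxels
  expect_identical(streamline_labels(sl, vol), 4L)
  expect_identical(bf_streamline_labels(sl, vol), 4L)
})

test_that("assignment agrees exactly with the brute-force oracle", {
  set.seed(77)
  arr <- array(0L, c(20, 20, 20))
  arr[9:11, 1:3, 9:11] <- 1L                   # seed
  arr[3:6, 16:19, 3:6] <- 2L                   # target
  arr[14:17, 16:19, 3:6] <- 3L                 # target
  arr[9:11, 16:19, 14:17] <- 4L                # target
  arr[9:11, 8:10, 15:17] <- 5L                 # exclusion, off the direct paths
  tab <- region_table(data.frame(
    label = 1:5,
    name = c("Seed", "Left A", "Right A", "Midline B", "Avoid"),
    hemisphere = c("midline", "left", "right", "midline", "midline"),
    compartment = c("none", "nuclear", "nuclear", "posterior", "none"),
    role = c("seed", "target", "target", "target", "exclusion")))
  th <- 0.2                                    # mildly oblique affine
  aff <- rbind(c(cos(th), -sin(th), 0, -5), c(sin(th), cos(th), 0, 2),
               c(0, 0, 1, -9), c(0, 0, 0, 1))
  vol <- label_volume(arr, aff)

  vox_world <- function(v) (aff %*% c(v, 1))[1:3]
  rnd <- function() vox_world(runif(3, 0, 19))
  sls <- c(
    # random 2-4 vertex polylines across the grid
    lapply(1:40, function(i) t(sapply(seq_len(sample(2:4, 1)),
                                      function(j) rnd()))),
    # forced cases: seed->one target, seed->two targets, through exclusion
    list(rbind(vox_world(c(10, 2, 10)), vox_world(c(4, 17, 4))),
         rbind(vox_world(c(4, 17, 4)), vox_world(c(15, 17, 4))),
         rbind(vox_world(c(10, 2, 10)), vox_world(c(10, 8, 15)),
               vox_world(c(10, 17, 15)))))
  tract <- tractogram(sls)
  asg <- assign_streamlines(tract, vol, tab)
  expect_identical(asg$outcome, bf_assign(tract, vol, tab))

  # the forced cases land where constructed
  n <- length(sls)
  expect_equal(asg$outcome[n - 2], "2")
  expect_equal(asg$outcome[n - 1], "multiple_targets")
  expect_equal(asg$outcome[n], "touches_exclusion")

  # partition: assigned + discarded = total
  expect_equal(sum(asg$counts) + sum(asg$discards), n)

  # order invariance: permuting streamlines permutes outcomes identically
  set.seed(3)
  perm <- sample(n)
  asg2 <- assign_streamlines(tractogram(sls[perm]), vol, tab)
  expect_identical(asg2$outcome, asg$outcome[perm])
  expect_identical(asg2$counts, asg$counts)
})

test_that("exclusion dominates and degenerate streamlines are counted", {
  arr <- array(0L, c(12, 12, 12))
  arr[2:3, 2:3, 2:3] <- 1L; arr[9:10, 9:10, 9:10] <- 2L
  arr[5:6, 5:6, 5:6] <- 3L
  tab <- tiny_region_table(n_targets = 1)     # labels: 1 seed, 2 target, 3 excl
  vol <- label_volume(arr, diag(4))
  # touches both the target and the exclusion: exclusion wins
  sl_both <- rbind(c(2, 2, 2), c(5.5, 5.5, 5.5), c(9, 9, 9))
  # single-vertex streamline, injected past the constructor
  bad <- structure(list(streamlines = list(sl_both, matrix(c(2, 2, 2), 1, 3)),
                        header = list()), class = "tractogram")
  asg <- assign_streamlines(bad, vol, tab)
  expect_equal(asg$outcome, c("touches_exclusion", "invalid"))
  expect_equal(unname(asg$discards["invalid"]), 1L)
  expect_equal(sum(asg$counts) + sum(asg$discards), 2L)
})

test_that("strict seed traversal discards streamlines that skip the seed", {
  arr <- array(0L, c(12, 12, 12))
  arr[2:3, 2:3, 2:3] <- 1L; arr[9:10, 9:10, 9:10] <- 2L; arr[1, 12, 12] <- 3L
  tab <- tiny_region_table(n_targets = 1)
  vol <- label_volume(arr, diag(4))
  sl <- rbind(c(6, 6, 6), c(9.5, 9.5, 9.5))   # reaches target, never the seed
  t1 <- assign_streamlines(tractogram(list(sl)), vol, tab)
  expect_equal(t1$outcome, "2")
  t2 <- assign_streamlines(tractogram(list(sl)), vol, tab, strict_seed = TRUE)
  expect_equal(t2$outcome, "no_seed")
})
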