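test_that("one-sample group t matches the closed form and conventions", {
  dims <- c(3, 3, 3)
  # all-zero maps -> all-zero t
  z <- lapply(1:4, function(i) array(0, dims))
  g0 <- one_sample_group_t(z)
  expect_equal(g0$t, array(0, dims))
  # n = 21 -> dof 20
  maps <- lapply(1:21, function(i) array(rnorm(27), dims))
  expect_equal(one_sample_group_t(maps)$dof, 20L)
  # closed-form oracle at one voxel
  vals <- c(1, 2, 3, 4, 5)
  maps5 <- lapply(vals, function(v) array(v, dims))
  g5 <- one_sample_group_t(maps5)
  t_ref <- mean(vals) / (sd(vals) / sqrt(5))
  expect_equal(g5$t[1, 1, 1], t_ref, tolerance = 1e-12)
  expect_error(one_sample_group_t(maps5[1]), ">= 2")
})

test_that("cluster labeling matches a brute-force BFS oracle", {
  bfs_components <- function(mask, conn) {
    # independent flood fill
    dims <- dim(mask)
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, ]
    if (conn == 6) offs <- offs[rowSums(abs(offs)) == 1, ]
    seen <- array(FALSE, dims)
    sizes <- integer(0)
    idx <- which(mask)
    coords <- arrayInd(idx, dims)
    for (s in seq_along(idx)) {
      if (seen[idx[s]]) next
      queue <- list(coords[s, ])
      seen[idx[s]] <- TRUE
      size <- 0L
      while (length(queue)) {
        c0 <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
        for (o in seq_len(nrow(offs))) {
          nc <- c0 + offs[o, ]
          if (any(nc < 1) || any(nc > dims)) next
          if (mask[nc[1], nc[2], nc[3]] && !seen[nc[1], nc[2], nc[3]]) {
            seen[nc[1], nc[2], nc[3]] <- TRUE
            queue[[length(queue) + 1]] <- nc
          }
        }
      }
      sizes <- c(sizes, size)
    }
    sort(sizes, decreasing = TRUE)
  }
  set.seed(7)
  for (rep in 1:5) {
    mask <- array(runif(10 * 9 * 8) < 0.18, c(10, 9, 8))
    for (conn in c(6, 26)) {
      lc <- label_clusters(mask, conn)
      expect_equal(lc$sizes, bfs_components(mask, conn),
                   info = sprintf("rep %d conn %d", rep, conn))
      expect_equal(sum(lc$labels > 0), sum(mask))
    }
  }
})

test_that("empty masks and subthreshold maps give empty results", {
  lc <- label_clusters(array(FALSE, c(4, 4, 4)))
  expect_equal(lc$sizes, integer(0))
  set.seed(1)
  maps <- lapply(1:8, function(i) array(rnorm(64, 0, 1e-3), c(4, 4, 4)))
  g <- one_sample_group_t(maps)
  g$t <- array(0, c(4, 4, 4))  # force nothing above threshold
  th <- suppressWarnings(
    threshold_with_cluster_fwe(g, maps, n_permutations = 128, seed = 1))
  expect_equal(sum(th$mask), 0L)
  expect_length(th$clusters, 0)
})

test_that("a planted strong blob and only that blob survives FWE", {
  set.seed(2)
  dims <- c(10, 10, 10)
  blob <- array(0, dims); blob[4:6, 4:6, 4:6] <- 2
  maps <- lapply(1:12, function(s) array(rnorm(1000, 0, 0.4), dims) + blob)
  g <- one_sample_group_t(maps)
  th <- threshold_with_cluster_fwe(g, maps, n_permutations = 500, seed = 3)
  expect_equal(length(th$cluster_sizes), 1L)
  expect_equal(sum(th$mask & blob > 0), 27L)
  expect_equal(sum(th$mask & blob == 0), 0L)
  expect_lt(th$cluster_p[1], 0.05)
})

test_that("few subjects trigger exhaustive enumeration with a warning", {
  set.seed(3)
  maps <- lapply(1:6, function(s) array(rnorm(125), c(5, 5, 5)))
  g <- one_sample_group_t(maps)
  expect_warning(
    th <- threshold_with_cluster_fwe(g, maps, n_permutations = 100, seed = 1),
    "exhaustive")
  expect_equal(th$n_permutations, 2^6)
  # exhaustive null is invariant to a global sign flip of all subject maps
  flipped <- lapply(maps, function(m) -m)
  gf <- one_sample_group_t(flipped)
  expect_warning(
    thf <- threshold_with_cluster_fwe(gf, flipped, n_permutations = 100,
                                      seed = 1), "exhaustive")
  expect_equal(sort(th$null_max_cluster_sizes),
               sort(thf$null_max_cluster_sizes))
})

test_that("thresholding is deterministic given the seed", {
  set.seed(8)
  maps <- lapply(1:10, function(s) array(rnorm(512, 0.4, 1), c(8, 8, 8)))
  g <- one_sample_group_t(maps)
  t1 <- threshold_with_cluster_fwe(g, maps, voxel_p = 0.01,
                                   n_permutations = 200, seed = 5)
  t2 <- threshold_with_cluster_fwe(g, maps, voxel_p = 0.01,
                                   n_permutations = 200, seed = 5)
  expect_identical(t1$mask, t2$mask)
  expect_identical(t1$null_max_cluster_sizes, t2$null_max_cluster_sizes)
  expect_error(threshold_with_cluster_fwe(g, maps, n_permutations = 50),
               ">= 100")
})

test_that("conjunction obeys set algebra", {
  set.seed(11)
  a <- array(runif(60) < 0.4, c(5, 4, 3))
  b <- array(runif(60) < 0.4, c(5, 4, 3))
  expect_equal(conjunction(a, a), a)
  expect_equal(conjunction(a, b), conjunction(b, a))
  expect_true(all(conjunction(a, b) <= a))
  expect_true(all(conjunction(a, b) <= b))
  expect_equal(sum(conjunction(a, !a)), 0L)
  expect_error(conjunction(a, array(TRUE, c(2, 2, 2))), "grid mismatch")
})

test_that("shared-ROI segmentation partitions the labeled mask", {
  at <- tiny_atlas(2)
  mask <- array(FALSE, dim(at$grid))
  mask[at$grid == 1L] <- TRUE
  mask[at$grid == 2L][1:5] <- NA # placeholder, replaced below
  mask <- at$grid > 0            # straddles both labels
  mask[1, 1, 1] <- TRUE          # background voxel -> logged, excluded
  rois <- segment_shared_rois(mask, at, min_voxels = 1)
  expect_named(rois, c("shared-R1", "shared-R2"))
  expect_equal(sum(vapply(rois, function(r) nrow(r$voxels), integer(1))),
               sum(mask) - 1L)
  expect_true(any(grepl("background", get_log())))
  # min_voxels drops small groups
  rois2 <- segment_shared_rois(mask, at, min_voxels = 1000)
  expect_length(rois2, 0)
  # empty mask -> empty list
  expect_length(segment_shared_rois(array(FALSE, dim(at$grid)), at), 0)
})
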