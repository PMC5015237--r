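mk_spect <- function(arr) sln_volume(arr, c(1, 1, 1), modality = "SPECT")

test_that("seed detection matches the exhaustive neighbourhood scan", {
  # single nonzero voxel
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 10
  s <- find_seeds(mk_spect(a))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$i, s$j, s$k), c(2, 2, 2))

  # two blobs separated by a zero gap
  b <- array(0, c(9, 5, 5))
  b[2, 3, 3] <- 5; b[3, 3, 3] <- 9; b[4, 3, 3] <- 5
  b[7, 3, 3] <- 7; b[8, 3, 3] <- 4
  s <- find_seeds(mk_spect(b))
  expect_equal(nrow(s), 2L)
  expect_equal(s$value, c(9, 7))  # sorted by descending value

  # all-zero volume: empty, not an error
  expect_equal(nrow(find_seeds(mk_spect(array(0, c(3, 3, 3))))), 0L)

  # randomized grids against the exhaustive-scan oracle
  set.seed(11)
  for (rep in 1:40) {
    v <- random_grid_volume(c(6, 6, 6), max_val = 4)
    got <- find_seeds(v)
    exp <- oracle_find_seeds(v$values)
    expect_equal(got$lin, exp$lin)
    expect_equal(got$value, exp$value)
  }
})

test_that("one seed per flat plateau, at the lexicographically smallest index", {
  a <- array(0, c(5, 5, 5))
  a[2:4, 2:4, 3] <- 6  # 3x3 plateau
  s <- find_seeds(mk_spect(a))
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$i, s$j, s$k), c(1, 1, 2))

  const <- mk_spect(array(2, c(4, 4, 4)))
  s <- find_seeds(const)
  expect_equal(nrow(s), 1L)
  expect_equal(c(s$i, s$j, s$k), c(0, 0, 0))
})

test_that("region growing follows non-increasing positive descent", {
  # strictly decreasing ridge: all nonzero voxels claimed
  a <- array(0, c(7, 3, 3))
  a[1:4, 2, 2] <- c(9, 7, 5, 3)
  v <- mk_spect(a)
  seed <- which(a == 9)
  expect_setequal(grow_region(v, seed), which(a > 0))

  # a rise beyond a valley is never crossed: {9,5,7} claims {9,5}
  b <- array(0, c(5, 3, 3))
  b[1:3, 2, 2] <- c(9, 5, 7)
  claimed <- grow_region(mk_spect(b), which(b == 9))
  expect_setequal(claimed, which(b %in% c(9, 5)))

  expect_error(grow_region(v, which(a == 0)[1]), "positive")

  # randomized grids against the monotone-path oracle
  set.seed(12)
  for (rep in 1:25) {
    g <- random_grid_volume(c(5, 5, 5), max_val = 4)
    seeds <- oracle_find_seeds(g$values)
    for (s in seeds$lin) {
      expect_equal(sort(grow_region(g, s)), oracle_grow(g$values, s))
    }
  }
})

test_that("segmentation deletes common voxels and stays disjoint", {
  # single blob: one hot spot, nothing removed
  a <- array(0, c(7, 7, 7))
  a[3:5, 3:5, 3:5] <- 1; a[4, 4, 4] <- 5
  hs <- segment_hotspots(mk_spect(a))
  expect_equal(nrow(hs$spots), 1L)
  expect_equal(hs$n_common, 0L)
  expect_equal(hs$spots$peak_value, 5)
  expect_equal(hs$spots$n_voxels, 27L)

  # two maxima over a shared saddle: saddle voxels vanish from both
  b <- array(0, c(9, 3, 3))
  b[1:7, 2, 2] <- c(3, 9, 3, 2, 3, 8, 3)
  hs <- segment_hotspots(mk_spect(b))
  expect_equal(nrow(hs$spots), 2L)
  expect_gt(hs$n_common, 0L)
  expect_length(intersect(hs$voxels[[1]], hs$voxels[[2]]), 0L)
  # the saddle voxel (value 2) was reachable from both: in neither
  expect_false(which(b == 2) %in% c(hs$voxels[[1]], hs$voxels[[2]]))

  # labels in descending peak order
  expect_equal(hs$spots$peak_value, c(9, 8))
  expect_equal(hs$spots$label, c(1L, 2L))
})

test_that("hot spot invariants hold on random grids", {
  set.seed(13)
  for (rep in 1:30) {
    v <- random_grid_volume(c(6, 6, 6), max_val = 4)
    hs <- segment_hotspots(v)
    all_vox <- unlist(hs$voxels)
    # disjointness
    expect_equal(anyDuplicated(all_vox), 0L)
    # union within the nonzero support
    expect_true(all(v$values[all_vox] > 0))
    # every hot spot contains exactly one seed
    seed_lins <- find_seeds(v)$lin
    for (q in seq_along(hs$voxels)) {
      expect_equal(sum(seed_lins %in% hs$voxels[[q]]), 1L)
    }
  }
})

test_that("segmentation equals the brute-force monotone-path construction", {
  set.seed(14)
  for (rep in 1:30) {
    v <- random_grid_volume(c(6, 6, 6), max_val = 4)
    got <- segment_hotspots(v)
    exp <- oracle_segment(v$values)
    expect_equal(nrow(got$spots), length(exp))
    for (q in seq_along(exp)) {
      expect_equal(got$spots$seed_lin[q], exp[[q]]$seed)
      expect_equal(sort(got$voxels[[q]]), exp[[q]]$voxels)
    }
  }
})

test_that("blurred-together maxima yield a single hot spot", {
  # two point sources closer than the resolution merge into one plateau
  a <- array(0, c(11, 11, 11))
  a[5, 6, 6] <- 10; a[7, 6, 6] <- 10; a[6, 6, 6] <- 10
  hs <- segment_hotspots(mk_spect(a))
  expect_equal(nrow(hs$spots), 1L)
})

test_that("hot spots export round-trips through JSON", {
  a <- array(0, c(5, 5, 5)); a[3, 3, 3] <- 10; a[3, 3, 2] <- 4
  hs <- segment_hotspots(mk_spect(a))
  js <- hotspots_to_json(hs)
  rec <- jsonlite::fromJSON(js)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$peak_value, 10)
  expect_equal(rec$n_voxels, 2L)
})
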