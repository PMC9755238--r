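test_that("claustrum frame matches the Chebyshev-distance definition", {
  # single claustrum voxel centred in an all-insular-WM 7^3 grid:
  # the radius-2 Chebyshev ball has 5^3 voxels, minus the claustrum itself
  sch <- phantom_scheme()
  grid <- array(scheme_id(sch, "insular_wm_left"), dim = c(7, 7, 7))
  grid[1, 1, 1] <- scheme_id(sch, "claustrum_right")
  grid[4, 4, 4] <- scheme_id(sch, "claustrum_left")
  vol <- label_volume(grid, scheme = sch)
  frame <- build_claustrum_frame(vol, "left")
  expect_equal(sum(frame$grid), 5^3 - 1)
  expect_true(all(which(frame$grid, arr.ind = TRUE) >= 2 &
                  which(frame$grid, arr.ind = TRUE) <= 6))

  # brute-force check on a random configuration
  set.seed(7)
  vol2 <- random_claustrum_volume()
  cla <- vol2$grid == scheme_id(sch, "claustrum_left")
  wm <- vol2$grid == scheme_id(sch, "insular_wm_left")
  expected <- dilate_oracle(cla, 2) & wm & !cla
  got <- build_claustrum_frame(vol2, "left")
  expect_identical(got$grid, expected)
})

test_that("frame is empty with a warning when insular WM is absent", {
  sch <- phantom_scheme()
  grid <- array(scheme_id(sch, "cortical_gm"), dim = c(5, 5, 5))
  grid[3, 3, 3] <- scheme_id(sch, "claustrum_left")
  grid[1, 1, 1] <- scheme_id(sch, "claustrum_right")
  vol <- label_volume(grid, scheme = sch)
  expect_warning(frame <- build_claustrum_frame(vol, "left"), "empty")
  expect_equal(sum(frame$grid), 0)
  # empty claustrum is an error, not a warning
  grid[3, 3, 3] <- scheme_id(sch, "cortical_gm")
  expect_error(build_claustrum_frame(label_volume(grid, scheme = sch),
                                     "left"),
               "no voxels")
})

test_that("controlled segmentation keeps only interior voxels", {
  sch <- phantom_scheme()
  block <- function(k) {
    d <- k + 4L
    grid <- array(scheme_id(sch, "white_matter"), dim = c(d, d, d))
    core <- 3:(2 + k)
    grid[core, core, core] <- scheme_id(sch, "claustrum_left")
    grid[1, 1, 1] <- scheme_id(sch, "claustrum_right")
    label_volume(grid, scheme = sch)
  }
  # solid 3^3: only the centre voxel has all 26 neighbours
  expect_equal(sum(build_claustrum_controlled(block(3), "left")$grid), 1)
  # solid 5^3: the interior 3^3 survives
  expect_equal(sum(build_claustrum_controlled(block(5), "left")$grid), 27)
  # default fraction 0.9 requires >= 24 of 26 neighbours
  ctrl <- build_claustrum_controlled(block(5), "left", fraction = 0.9)
  cla <- block(5)$grid == scheme_id(sch, "claustrum_left")
  counts <- count26_oracle(cla)
  expect_identical(ctrl$grid, cla & counts >= 24L)
})

test_that("controlled mask is monotone in the fraction threshold", {
  set.seed(11)
  for (rep in 1:5) {
    vol <- random_claustrum_volume()
    strict <- build_claustrum_controlled(vol, "left", fraction = 1.0)$grid
    loose <- build_claustrum_controlled(vol, "left", fraction = 0.9)$grid
    expect_true(all(!strict | loose))
  }
})

test_that("dilation and neighbour counts equal brute-force oracles", {
  set.seed(42)
  for (rep in 1:6) {
    dims <- sample(5:16, 3, replace = TRUE)
    mask <- array(runif(prod(dims)) < 0.25, dim = dims)
    expect_identical(dilate_chebyshev(mask, 1), dilate_oracle(mask, 1))
    expect_identical(dilate_chebyshev(mask, 2), dilate_oracle(mask, 2))
    expect_identical(neighbor_count26(mask), count26_oracle(mask))
  }
})

test_that("mask operators are invariant to translation and axis flips", {
  set.seed(5)
  vol <- random_claustrum_volume(c(14L, 14L, 14L))
  frame <- build_claustrum_frame(vol, "left")$grid
  ctrl <- build_claustrum_controlled(vol, "left")$grid

  shift_vol <- function(vol, s) {
    bg <- scheme_id(vol$scheme, "white_matter")
    g <- array(bg, dim = dim(vol$grid) + 2L * abs(s))
    g[abs(s[1]) + s[1] + 1:14, abs(s[2]) + s[2] + 1:14,
      abs(s[3]) + s[3] + 1:14] <- vol$grid
    label_volume(g, scheme = vol$scheme)
  }
  s <- c(2L, -1L, 3L)
  vs <- shift_vol(vol, s)
  fs <- build_claustrum_frame(vs, "left")$grid
  expect_equal(sum(fs), sum(frame))
  expect_identical(fs[abs(s[1]) + s[1] + 1:14, abs(s[2]) + s[2] + 1:14,
                      abs(s[3]) + s[3] + 1:14], frame)

  flip <- function(a) a[dim(a)[1]:1, , ]
  vf <- label_volume(flip(vol$grid), scheme = vol$scheme)
  expect_identical(flip(build_claustrum_frame(vf, "left")$grid), frame)
  expect_identical(flip(build_claustrum_controlled(vf, "left")$grid), ctrl)
})
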