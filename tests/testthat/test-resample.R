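test_that("rotation angles are one step in each direction", {
  expect_equal(rotation_angles(15), c(-15, 0, 15))
  expect_equal(rotation_angles(0), 0)
  for (th in c(1, 7.5, 30, 44)) {
    a <- rotation_angles(th)
    expect_length(a, 3)
    expect_equal(a, -rev(a))  # symmetric about 0
  }
  expect_error(rotation_angles(-1), ">= 0")
})

test_that("max patch side matches closed forms and a corner-tracing oracle", {
  expect_equal(max_valid_patch_side(c(512, 512), 0, 0), 512)
  expect_equal(max_valid_patch_side(c(512, 512), 45, 0), floor(512 / sqrt(2)))
  for (case in list(list(sz = c(768, 1024), th = 15, off = 20),
                    list(sz = c(100, 140), th = 15, off = 5),
                    list(sz = c(90, 120), th = 30, off = 0))) {
    truth <- brute_force_max_side(case$sz, case$th, case$off)
    got <- max_valid_patch_side(case$sz, case$th, case$off)
    expect_lte(got, truth)        # never exceeds the true sampling bound
    expect_lte(truth - got, 2)    # and is tight to within 2 px
  }
})

test_that("patch extraction equals plain crop at angle 0 and the pixel oracle", {
  img <- with_seed(5, array(stats::runif(80 * 100 * 3, 0, 255), c(80, 100, 3)))
  p <- extract_rotated_patch(img, c(40.5, 50.5), 0, c(30, 40))
  expect_identical(p, img[26:55, 31:70, , drop = FALSE])
  g <- outer(seq_len(80), seq_len(100), function(r, c) 2 * r + 3 * c)
  gi <- array(c(g, g / 2, g / 3), c(80, 100, 3))
  fast <- extract_rotated_patch(gi, c(40.2, 50.7), 15, c(24, 24))
  slow <- slow_rotated_patch(gi, c(40.2, 50.7), 15, c(24, 24))
  expect_lt(max(abs(fast - slow)), 1e-4)
})

test_that("rotating forward then backward recovers the center crop", {
  g <- outer(seq_len(100), seq_len(100),
             function(r, c) 50 * sin(r / 15) + 40 * cos(c / 12))
  img <- array(rep(g, 3), c(100, 100, 3))
  big <- extract_rotated_patch(img, c(50.5, 50.5), 15, c(60, 60))
  back <- extract_rotated_patch(big, c(30.5, 30.5), -15, c(30, 30))
  ref <- extract_rotated_patch(img, c(50.5, 50.5), 0, c(30, 30))
  expect_lt(max(abs(back - ref)) / diff(range(img)), 2e-3)
})

test_that("out-of-bounds patch requests error instead of padding", {
  img <- array(0, c(50, 50, 3))
  expect_error(extract_rotated_patch(img, c(25, 25), 0, c(60, 60)),
               "refusing to pad")
  expect_error(extract_rotated_patch(img, c(5, 5), 15, c(20, 20)),
               "refusing to pad")
})

test_that("offset centers start at the center and fill the disc uniformly", {
  ctr <- c(100, 120)
  expect_equal(sample_offset_centers(ctr, 1, 50, 1), matrix(ctr, 1, 2))
  z <- sample_offset_centers(ctr, 15, 0, 2)
  expect_equal(z, matrix(rep(ctr, each = 15), 15, 2))
  big <- sample_offset_centers(ctr, 1000, 20, 3)
  expect_equal(big[1, ], ctr)
  d <- sqrt((big[, 1] - ctr[1])^2 + (big[, 2] - ctr[2])^2)
  expect_lte(max(d), 20)
  # mean distance of a uniform disc draw is 2/3 of the radius
  expect_lt(abs(mean(d[-1]) - 2 / 3 * 20), 0.5)
})

test_that("expand_case obeys the 3 x Nt count law and stays in bounds", {
  cfg <- resampling_config()
  mk <- function(label) {
    m <- generate_manifest(
      stats::setNames(as.numeric(oral_classes() == label), NULL),
      canvas = c(96, 128), rng_seed = 21)
    render_manifest_image(m, 1)
  }
  cancer <- expand_case(mk("cancer"), cfg, 1)
  expect_length(cancer$patches, 45)  # 3 angles x 15 centers
  normal <- expand_case(mk("normal"), cfg, 1)
  expect_length(normal$patches, 3)   # rotations only for normals
  ulcer <- expand_case(mk("ulcer"), cfg, 1)
  expect_length(ulcer$patches, 9)
  side <- unique(vapply(ulcer$patches, function(p) dim(p)[1], 0L))
  # default geometry: s * (cos t + sin t + 0.1) <= min(H, W)
  expect_equal(side, floor(96 / (cospi(15 / 180) + sinpi(15 / 180) + 0.1)))
})

test_that("no patch ever samples a sentinel border pixel", {
  with_seed(31, {
    for (rep in 1:40) {
      H <- sample(40:90, 1); W <- sample(40:90, 1)
      th <- stats::runif(1, 0, 30)
      inner <- c(H - 4, W - 4)
      off <- stats::runif(1, 0, 6)
      side <- max_valid_patch_side(inner, th, off)
      if (side < 4) next
      img <- array(1e6, c(H, W, 3))
      img[3:(H - 2), 3:(W - 2), ] <- 0
      ctr0 <- c((H + 1) / 2, (W + 1) / 2)
      centers <- sample_offset_centers(ctr0, 5, off, rep)
      for (j in seq_len(nrow(centers))) {
        for (ang in rotation_angles(th)) {
          p <- extract_rotated_patch(img, centers[j, ], ang, c(side, side))
          expect_lt(max(p), 1)
        }
      }
    }
  })
})

test_that("training-set expansion follows base x 3 x Nt for any manifest", {
  cfg <- resampling_config()
  for (s in 1:5) {
    n <- with_seed(s, sample(0:8, 5, replace = TRUE))
    m <- generate_manifest(n, canvas = c(192, 256), rng_seed = s)
    if (nrow(m) == 0) next
    bt <- build_training_set(m, cfg, rng_seed = s)
    mult <- c(3, 9, 9, 15, 45)  # 3 x Nt with Nt(normal) = 1
    expect_equal(unname(bt$counts$expanded), unname(bt$counts$base * mult))
    expect_equal(nrow(bt$manifest), sum(bt$counts$expanded))
  }
})

test_that("empty training split expands to an empty set", {
  m <- generate_manifest(c(2, 1, 0, 0, 0), rng_seed = 1)
  m$split <- "test"
  bt <- build_training_set(m, resampling_config(), 1)
  expect_equal(sum(bt$counts$expanded), 0)
  expect_equal(nrow(bt$manifest), 0)
})

test_that("expanded patch rows materialize and differ across angles", {
  m <- generate_manifest(c(0, 2, 0, 0, 0), canvas = c(96, 128), rng_seed = 9)
  bt <- build_training_set(m, resampling_config(), 4)
  src <- render_manifest_image(bt$manifest, 1)
  p1 <- extract_patch_row(bt$manifest, 1, src)
  p2 <- extract_patch_row(bt$manifest, 2, src)
  expect_equal(dim(p1), dim(p2))
  expect_false(identical(p1, p2))
  # the angle-0, zero-offset row equals the plain centered crop
  zero <- which(bt$manifest$angle == 0 &
                  bt$manifest$patch_row == (96 + 1) / 2 &
                  bt$manifest$patch_col == (128 + 1) / 2)[1]
  pz <- extract_patch_row(bt$manifest, zero)
  srcz <- render_manifest_image(bt$manifest, zero)
  expect_equal(pz, extract_rotated_patch(srcz, c(48.5, 64.5), 0, dim(pz)[1:2]))
})

test_that("random oversampling balances counts and preserves originals", {
  m <- generate_manifest(c(10, 2, 0, 0, 0), rng_seed = 2)
  b <- random_oversample(m, 1)
  expect_equal(unname(class_counts(b))[1:2], c(10L, 10L))
  expect_true(all(m$sample_id %in% b$sample_id))
  expect_true(all(b$sample_id %in% m$sample_id))
  # already balanced input is unchanged
  m2 <- generate_manifest(c(4, 4, 4, 4, 4), rng_seed = 3)
  expect_equal(nrow(random_oversample(m2, 1)), nrow(m2))
  # bookkeeping at the study's class ratio
  m3 <- generate_manifest(c(53, 17, 16, 9, 4), rng_seed = 4)
  b3 <- random_oversample(m3, 9)
  expect_equal(unname(class_counts(b3)), rep(53L, 5))
  expect_equal(sort(unique(b3$sample_id)), sort(m3$sample_id))
})
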