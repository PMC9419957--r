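test_that("sphere masks follow the affine geometry", {
  aff <- diag(c(2, 2, 2, 1))  # 2 mm isotropic, origin at voxel (0,0,0)
  shp <- c(21, 21, 21)
  ctr <- c(20, 20, 20)        # on a voxel center
  # radius below half a voxel: exactly the center voxel
  m1 <- sphere_mask(ctr, 0.9, aff, shp)
  expect_equal(nrow(m1$subscripts), 1)
  expect_equal(m1$subscripts[1, ], c(10, 10, 10))
  # 6 mm radius on a 2 mm grid: brute-force offset count
  m6 <- sphere_mask(ctr, 6, aff, shp)
  offs <- expand.grid(-3:3, -3:3, -3:3)
  expect_equal(nrow(m6$subscripts), sum(rowSums(offs^2) <= 9))
  # translating the center by one voxel translates the mask
  m6b <- sphere_mask(ctr + c(2, 0, 0), 6, aff, shp)
  expect_setequal(m6b$subscripts[, 1], m6$subscripts[, 1] + 1)
  expect_equal(sort(m6b$index),
               sort(m6$index + 1L))
  expect_error(sphere_mask(c(500, 0, 0), 6, aff, shp), "outside")
  expect_error(sphere_mask(ctr, 6, matrix(0, 4, 4), shp), "invertible")
})

test_that("eigenvariates summarize voxel blocks along the leading component", {
  set.seed(1)
  Tn <- 80
  ts <- sin(seq_len(Tn) / 5)
  w <- runif(12, 0.5, 2)
  blk <- ts %o% w
  ev <- eigenvariate(blk)
  expect_gt(stats::cor(ev, ts), 1 - 1e-10)
  expect_equal(stats::sd(ev), 1)
  # sign convention: positive mean loading
  ev_neg <- eigenvariate(ts %o% (-w))
  expect_gt(stats::cor(ev_neg, -ts), 1 - 1e-10)
  # single voxel: its standardized series
  one <- eigenvariate(matrix(ts, ncol = 1))
  expect_gt(stats::cor(one, ts), 0.999)
  expect_equal(stats::sd(one), 1)
  # Monte-Carlo: no random unit projection explains more variance than the
  # direction the eigenvariate corresponds to
  set.seed(2)
  X <- matrix(rnorm(60 * 8), 60, 8) %*% matrix(rnorm(64), 8, 8)
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigenvariate(X)
  u1 <- as.numeric(crossprod(Xc, ev))
  u1 <- u1 / sqrt(sum(u1^2))
  var_pc <- sum((Xc %*% u1)^2)
  best_rand <- max(vapply(seq_len(1000), function(i) {
    u <- rnorm(8); u <- u / sqrt(sum(u^2))
    sum((Xc %*% u)^2)
  }, numeric(1)))
  expect_gte(var_pc, best_rand)
  expect_error(eigenvariate(matrix(1, 10, 3)), "constant")
})

test_that("nuisance regression projects out confounds exactly", {
  set.seed(3)
  Tn <- 120
  conf <- cbind(a = rnorm(Tn), b = cumsum(rnorm(Tn)) / 5)
  y <- matrix(rnorm(Tn * 3), Tn, 3) + conf %*% matrix(rnorm(6), 2, 3)
  res <- nuisance_regress(y, conf)
  expect_lt(max(abs(crossprod(res, conf))), 1e-8)
  expect_lt(max(abs(colMeans(res))), 1e-12)
  # idempotence
  expect_equal(nuisance_regress(res, conf), res, tolerance = 1e-10)
  # a series equal to a confound column vanishes
  res2 <- nuisance_regress(cbind(conf[, 1]), conf)
  expect_lt(max(abs(res2)), 1e-10)
  # orthogonal confounds leave the series demeaned
  yo <- matrix(rnorm(Tn * 2), Tn, 2)
  co <- qr.resid(qr(cbind(1, yo)), rnorm(Tn))
  res3 <- nuisance_regress(yo, cbind(co))
  expect_equal(res3, sweep(yo, 2, colMeans(yo)), tolerance = 1e-8)
  expect_error(nuisance_regress(y, cbind(conf, conf[, 1])), "collinear|rank")
})

test_that("ROI extraction recovers signals placed in spheres", {
  set.seed(4)
  # small 4 mm grid covering the default ROI and WM/CSF spheres
  aff <- rbind(c(4, 0, 0, -64), c(0, 4, 0, -84), c(0, 0, 4, -42),
               c(0, 0, 0, 1))
  shp <- c(34, 39, 27)
  Tn <- 120
  spec <- network_spec()
  vol <- array(rnorm(prod(shp) * Tn, 0, 0.05), c(shp, Tn))
  sigs <- matrix(rnorm(Tn * 8), Tn, 8)
  vmat <- matrix(vol, prod(shp), Tn)
  for (r in 1:8) {
    m <- sphere_mask(spec$mni_centers[r, ], spec$radius_mm, aff, shp)
    vmat[m$index + 1L, ] <- vmat[m$index + 1L, ] +
      matrix(sigs[, r], nrow(m$subscripts), Tn, byrow = TRUE)
  }
  vol <- array(vmat, c(shp, Tn))
  out <- extract_roi_series(vol, aff, spec, wm_csf = NULL)
  expect_identical(colnames(out), spec$roi_names)
  expect_equal(ncol(out), 8)
  for (r in 1:8)
    expect_gt(abs(stats::cor(out[, r], sigs[, r])), 0.99)
  # regressing confounds unrelated to the signals barely changes them
  motion <- matrix(rnorm(Tn * 12), Tn, 12)
  out1 <- extract_roi_series(vol, aff, spec, wm_csf = NULL, motion = motion)
  for (r in 1:8)
    expect_gt(abs(stats::cor(out1[, r], out[, r])), 0.9)
  # WM/CSF sphere eigenvariates come from the printed coordinates
  out2 <- extract_roi_series(vol, aff, spec)
  expect_equal(dim(out2), dim(out))
})

test_that("direct ROI series and rendered-volume extraction agree", {
  set.seed(5)
  cfg <- cohort_config(n_rois = 2, n_volumes = 128, seed = 9,
                       between_subject_sd = 0)
  tr <- make_ground_truth(cfg)
  rec <- simulate_subject(tr, 1, "LR", 1)
  ser <- rec$series[[1]]
  spec2 <- network_spec(roi_names = c("A", "B"),
                        mni_centers = rbind(c(0, 0, 0), c(24, 0, 0)),
                        radius_mm = 6)
  aff <- rbind(c(4, 0, 0, -20), c(0, 4, 0, -20), c(0, 0, 4, -20),
               c(0, 0, 0, 1))
  shp <- c(16, 11, 11)
  vmat <- matrix(rnorm(prod(shp) * nrow(ser), 0, 1e-4), prod(shp), nrow(ser))
  for (r in 1:2) {
    m <- sphere_mask(spec2$mni_centers[r, ], 6, aff, shp)
    vmat[m$index + 1L, ] <- vmat[m$index + 1L, ] +
      matrix(ser[, r], nrow(m$subscripts), nrow(ser), byrow = TRUE)
  }
  vol <- array(vmat, c(shp, nrow(ser)))
  out <- extract_roi_series(vol, aff, spec2, wm_csf = NULL)
  for (r in 1:2)
    expect_gt(abs(stats::cor(out[, r], ser[, r])), 0.99)
})
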