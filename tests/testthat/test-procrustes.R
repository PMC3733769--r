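test_that("centroid size matches its definition and is homogeneous", {
  square <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  expect_equal(centroid_size(square), sqrt(8))
  expect_equal(centroid_size(rbind(c(0, 0), c(2, 0))), sqrt(2))
  set.seed(5)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(centroid_size(3.7 * x), 3.7 * centroid_size(x))
  expect_error(centroid_size(rbind(c(1, 1), c(1, 1))), "degenerate")
})

test_that("GPA removes an exact rigid-similarity difference", {
  set.seed(8)
  base <- matrix(rnorm(12), 6, 2)
  th <- pi / 6
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  other <- sweep(2 * base %*% rot, 2, c(5, 7), "+")
  ds <- landmark_dataset(
    array(c(base, other), c(6, 2, 2)),
    labels = paste0("R", 1:6), roles = rep("reference", 6),
    specimen = c("a", "b"))
  fit <- gpa(ds)
  expect_lt(sum((fit$aligned_reference[, , 1] -
                 fit$aligned_reference[, , 2])^2), 1e-18)
  # fit invariants: centered, unit-size consensus, proper rotations
  for (i in 1:2) {
    expect_lt(max(abs(colMeans(fit$aligned_reference[, , i]))), 1e-9)
    expect_equal(det(fit$rotations[[i]]), 1, tolerance = 1e-12)
    expect_equal(crossprod(fit$rotations[[i]]), diag(2), tolerance = 1e-12)
  }
  expect_equal(centroid_size(fit$consensus), 1, tolerance = 1e-9)
})

test_that("an already centered, unit-size, aligned dataset is a fixed
           point of GPA", {
  set.seed(9)
  base <- matrix(rnorm(10), 5, 2)
  base <- sweep(base, 2, colMeans(base))
  base <- base / centroid_size(base)
  coords <- array(rep(base, 3), c(5, 2, 3))
  ds <- landmark_dataset(coords, paste0("R", 1:5), rep("reference", 5),
                         c("a", "b", "c"))
  fit <- gpa(ds)
  for (i in 1:3)
    expect_equal(fit$aligned_reference[, , i], base, tolerance = 1e-9,
                 ignore_attr = TRUE)
})

test_that("GPA consensus recovers the generating mean shape under
           isotropic noise", {
  # 50 specimens = mean shape + N(0, 0.01^2) noise, no nuisance;
  # oracle = the generating mean, aligned to the consensus
  sigma <- 0.01
  n <- 50
  set.seed(123)
  mean_shape <- cbind(cos(2 * pi * (0:5) / 6), sin(2 * pi * (0:5) / 6))
  coords <- array(NA_real_, c(6, 2, n))
  for (i in seq_len(n))
    coords[, , i] <- mean_shape + matrix(rnorm(12, 0, sigma), 6, 2)
  ds <- landmark_dataset(coords, paste0("R", 1:6), rep("reference", 6),
                         sprintf("s%02d", 1:n))
  fit <- gpa(ds)
  truth <- sweep(mean_shape, 2, colMeans(mean_shape))
  truth <- truth / centroid_size(truth)
  rot <- svd(crossprod(truth, fit$consensus))
  r <- rot$u %*% t(rot$v)
  if (det(r) < 0) r <- rot$u %*% diag(c(1, -1)) %*% t(rot$v)
  expect_lt(max(abs(truth %*% r - fit$consensus)), 3 * sigma / sqrt(n))
})

test_that("GPA output is invariant to per-configuration rigid-similarity
           pre-transforms", {
  sim <- make_noise_dataset(n = 8, seed = 21, noise_sd = 1)
  fit1 <- gpa(sim$dataset)
  fit2 <- gpa(perturb_rigid(sim$dataset, seed = 99))
  # compare in a common orientation: rotate fit2's aligned set onto fit1's
  for (i in seq_len(n_configurations(sim$dataset))) {
    a <- fit1$aligned_reference[, , i]
    b <- fit2$aligned_reference[, , i]
    s <- svd(crossprod(b, fit1$consensus))
    r <- s$u %*% t(s$v)
    if (det(r) < 0) r <- s$u %*% diag(c(1, -1)) %*% t(s$v)
    expect_lt(max(abs(b %*% r - a)), 1e-6)
  }
})

test_that("transfer applies exactly the reference transform", {
  # measurement points duplicated from reference landmarks: transferred
  # coordinates equal the aligned reference coordinates
  set.seed(31)
  n <- 4
  coords <- array(NA_real_, c(8, 2, n))
  for (i in seq_len(n)) {
    ref <- matrix(rnorm(8, sd = 2), 4, 2)
    coords[, , i] <- rbind(ref, ref)
  }
  ds <- landmark_dataset(coords, c(paste0("R", 1:4), paste0("MP", 1:4)),
                         rep(c("reference", "measurement"), each = 4),
                         sprintf("s%d", 1:n))
  fit <- gpa(ds)
  al <- transfer(fit, ds)
  expect_equal(al$coords, fit$aligned_reference, tolerance = 1e-9,
               ignore_attr = TRUE)

  # translation-only differences vanish entirely
  shifted <- ds
  shifted$coords[, 1, 2] <- shifted$coords[, 1, 1] + 13
  shifted$coords[, 2, 2] <- shifted$coords[, 2, 1] - 4
  ds2 <- landmark_dataset(shifted$coords, ds$labels, ds$roles,
                          ds$specimen, ds$replicate)
  fit2 <- gpa(ds2)
  al2 <- transfer(fit2, ds2)
  expect_equal(al2$coords[, , 1], al2$coords[, , 2], tolerance = 1e-9)

  # mismatched dataset is refused
  expect_error(transfer(fit, subset_specimens(ds, c("s1", "s2"))),
               "mismatch")
})

test_that("transferred coordinates match the nuisance-free generation when
           noise is zero", {
  spec <- synthetic_spec(n_specimens = 6, k_reference = 7,
                         modules = list(c("MP1", "MP2")),
                         k_measurement = 4, module_effect_sd = 0,
                         noise_sd = 0, digitization_sd = 0,
                         replicates = 1, seed = 77)
  sim <- generate_landmarks(spec)
  fit <- gpa(sim$dataset)
  al <- transfer(fit, sim$dataset)
  # every specimen is the same shape up to nuisance, so all transferred
  # configurations must coincide
  for (i in 2:6)
    expect_lt(max(abs(al$coords[, , i] - al$coords[, , 1])), 1e-9)
  # and match the generator's pre-nuisance truth up to the consensus
  # similarity (center, scale, rotate truth onto the transferred set)
  truth <- sim$truth[, , 1]
  ref_truth <- mcnet:::.template_shape(7, 4)$reference
  ctr <- colMeans(ref_truth)
  cs <- centroid_size(ref_truth)
  tr_truth <- sweep(truth, 2, ctr) / cs
  s <- svd(crossprod(sweep(ref_truth, 2, ctr) / cs, fit$consensus))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) r <- s$u %*% diag(c(1, -1)) %*% t(s$v)
  expect_lt(max(abs(tr_truth %*% r - al$coords[, , 1])), 1e-6)
})

test_that("Procrustes ANOVA flags zero error, preserves additivity, and
           detects individual variation", {
  # identical replicates: SS_error = 0, F infinite
  sim <- make_noise_dataset(n = 5, r = 1, seed = 41, noise_sd = 1)
  ds <- sim$dataset
  dup <- landmark_dataset(
    ds$coords[, , rep(seq_len(n_configurations(ds)), each = 2)],
    ds$labels, ds$roles,
    rep(ds$specimen, each = 2), rep(1:2, n_configurations(ds)))
  fit <- gpa(dup)
  al <- transfer(fit, dup)
  tab <- procrustes_anova(al)
  expect_equal(tab$SS[tab$effect == "error"], 0, tolerance = 1e-18)
  expect_true(is.infinite(tab$F[tab$effect == "individual"]))

  # strong individual effect, small error: F >> 1, SS additive
  spec <- synthetic_spec(n_specimens = 24, k_reference = 6,
                         modules = list(), k_measurement = 5,
                         module_effect_sd = 0, noise_sd = 0.05 * 100,
                         digitization_sd = 0.005 * 100, replicates = 2,
                         seed = 42)
  sim2 <- generate_landmarks(spec)
  al2 <- transfer(gpa(sim2$dataset), sim2$dataset)
  tab2 <- procrustes_anova(al2)
  ss <- tab2$SS
  expect_equal(ss[1] + ss[2], ss[3], tolerance = 1e-9)
  expect_gt(tab2$F[1], 10)

  # guard rails
  al_single <- transfer(gpa(sim$dataset), sim$dataset)
  expect_error(procrustes_anova(al_single), "replicates")
})
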