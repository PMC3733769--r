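test_that("Rv equals 1 for a block against itself and any similarity image
           of itself", {
  set.seed(2)
  x <- matrix(rnorm(20), 10, 2)
  expect_equal(rv_coefficient(x, x), 1, tolerance = 1e-12)
  th <- 0.7
  q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(rv_coefficient(x, 3.2 * x %*% q), 1, tolerance = 1e-12)
})

test_that("Rv matches a brute-force trace computation on fixed integer
           blocks", {
  x <- cbind(c(1, 2, 3, 5), c(0, 1, 4, 2))
  y <- cbind(c(2, 0, 1, 3), c(1, 1, 0, 5))
  # independent oracle: explicit centered matrix products and traces
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  sxy <- t(xc) %*% yc
  syx <- t(yc) %*% xc
  sxx <- t(xc) %*% xc
  syy <- t(yc) %*% yc
  oracle <- sum(diag(sxy %*% syx)) /
    sqrt(sum(diag(sxx %*% sxx)) * sum(diag(syy %*% syy)))
  expect_equal(rv_coefficient(x, y), oracle, tolerance = 1e-14)
  expect_equal(rv_coefficient(y, x), rv_coefficient(x, y))
})

test_that("Rv is invariant to rotation, translation, and positive scaling
           of either block, and bounded in [0, 1]", {
  set.seed(33)
  for (rep in 1:20) {
    x <- matrix(rnorm(16), 8, 2)
    y <- matrix(rnorm(16), 8, 2)
    v <- rv_coefficient(x, y)
    expect_gte(v, 0)
    expect_lte(v, 1)
    th <- runif(1, -pi, pi)
    q <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    y2 <- sweep(runif(1, 0.1, 10) * y %*% q, 2, rnorm(2, sd = 50), "+")
    expect_equal(rv_coefficient(x, y2), v, tolerance = 1e-12)
  }
  expect_error(rv_coefficient(matrix(0, 5, 2), matrix(rnorm(10), 5, 2)),
               "zero-variance")
  expect_error(rv_coefficient(matrix(rnorm(10), 5, 2),
                              matrix(rnorm(8), 4, 2)), "shape")
})

test_that("rv_matrix is the element-wise application of rv_coefficient
           over all pairs", {
  sim <- make_noise_dataset(n = 10, k_mp = 5, seed = 14, noise_sd = 2)
  al <- transfer(gpa(sim$dataset), sim$dataset)
  rv <- rv_matrix(al)
  expect_equal(rv$labels, paste0("MP", 1:5))
  expect_equal(diag(rv$values), setNames(rep(1, 5), rv$labels))
  expect_equal(rv$values, t(rv$values))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(rv$values[i, j],
                 rv_coefficient(t(al$coords[i, , ]), t(al$coords[j, , ])),
                 tolerance = 1e-14)
  }
})

test_that("a measurement block equal to another rotated 90 degrees gives
           Rv = 1 in the matrix", {
  set.seed(15)
  n <- 12
  a <- matrix(rnorm(2 * n), n, 2)
  b <- a %*% matrix(c(0, 1, -1, 0), 2, 2) # 90 degree rotation
  coords <- array(NA_real_, c(2, 2, n))
  coords[1, , ] <- t(a)
  coords[2, , ] <- t(b)
  al <- structure(list(coords = coords, labels = c("A", "B"),
                       specimen = sprintf("s%d", 1:n),
                       replicate = rep(1L, n)),
                  class = "aligned_dataset")
  rv <- rv_matrix(al)
  expect_equal(rv$values["A", "B"], 1, tolerance = 1e-12)
})

test_that("replicate averaging is the default and uses specimen means", {
  sim <- make_noise_dataset(n = 6, r = 2, k_mp = 4, seed = 16,
                            noise_sd = 2)
  al <- transfer(gpa(sim$dataset), sim$dataset)
  rv_mean <- rv_matrix(al, "specimen_means")
  expect_equal(rv_mean$n_specimens, 6L)
  rv_all <- rv_matrix(al, "all_replicates")
  expect_equal(rv_all$n_specimens, 12L)
})

test_that("within-module Rv exceeds between-module Rv on planted 2-module
           data", {
  spec <- synthetic_spec(n_specimens = 50, k_reference = 6,
                         modules = list(paste0("MP", 1:3),
                                        paste0("MP", 4:6)),
                         module_effect_sd = 5, noise_sd = 1,
                         digitization_sd = 0, replicates = 1, seed = 60)
  sim <- generate_landmarks(spec)
  al <- transfer(gpa(sim$dataset), sim$dataset)
  rv <- rv_matrix(al)
  within <- c(rv$values[1:3, 1:3][upper.tri(diag(3))],
              rv$values[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(rv$values[1:3, 4:6])
  expect_gt(mean(within), mean(between))
})

test_that("thresholding retains strictly-above-tau edges, keeps isolated
           nodes, and is monotone in tau", {
  vals <- diag(3)
  vals[1, 2] <- vals[2, 1] <- 0.5
  vals[1, 3] <- vals[3, 1] <- 0.1
  vals[2, 3] <- vals[3, 2] <- 0.25
  rv <- rv_matrix_obj(vals, c("MP1", "MP2", "MP3"))
  net <- threshold_network(rv, 0.2)
  expect_equal(n_edges(net), 2L)
  expect_equal(net$weights["MP1", "MP2"], 0.5)
  expect_equal(net$weights["MP2", "MP3"], 0.25)
  expect_equal(net$weights["MP1", "MP3"], 0)

  # boundary is strict: an edge exactly at tau is cut
  net_b <- threshold_network(rv, 0.25)
  expect_equal(n_edges(net_b), 1L)

  # no threshold: complete graph
  full <- threshold_network(rv, NULL)
  expect_equal(n_edges(full), 3L)
  expect_null(full$tau)

  # tau >= 1: no edges, nodes kept, with a warning
  expect_warning(net99 <- threshold_network(rv, 1), "no edges")
  expect_equal(n_edges(net99), 0L)
  expect_equal(net99$labels, rv$labels)

  # monotone edge sets, surviving weights unchanged
  set.seed(71)
  k <- 8
  m <- matrix(runif(k * k), k, k)
  m <- (m + t(m)) / 2
  diag(m) <- 1
  rvr <- rv_matrix_obj(m)
  taus <- sort(runif(5))
  prev <- threshold_network(rvr, taus[1])
  for (tau in taus[-1]) {
    cur <- threshold_network(rvr, tau)
    kept <- cur$weights > 0
    expect_true(all(prev$weights[kept] == cur$weights[kept]))
    expect_true(all(cur$weights[kept] == rvr$values[kept]))
    expect_lte(n_edges(cur), n_edges(prev))
    prev <- cur
  }
})

test_that("the full measurement-point design yields k(k-1)/2 computed
           pairs", {
  sim <- generate_landmarks(paper_shaped_spec("oexcavata_like", seed = 5))
  al <- transfer(gpa(sim$dataset), sim$dataset)
  rv <- rv_matrix(al)
  expect_equal(length(rv$labels), 19L)
  expect_equal(sum(upper.tri(rv$values)), 171L)
  expect_true(all(rv$values >= 0 & rv$values <= 1))
})
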