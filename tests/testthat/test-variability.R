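test_that("non-overlapping segmentation follows floor(T/l) with remainder discarded", {
  x <- matrix(rnorm(200 * 4), 200, 4)
  expect_length(segment_windows(x, 20), 10)
  w11 <- segment_windows(x, 11)
  expect_length(w11, 18)
  expect_equal(w11[[1]], x[1:11, ], ignore_attr = TRUE)
  expect_equal(w11[[18]], x[188:198, ], ignore_attr = TRUE)
  expect_error(segment_windows(x[1:25, ], 20), "N >= 2|N = 1")
  expect_error(segment_windows(x, 2), ">= 3")
})

test_that("window FC is plain signed Pearson correlation", {
  set.seed(2)
  b <- matrix(rnorm(20 * 5), 20, 5)
  b[, 2] <- b[, 1]        # identical pair
  b[, 4] <- -b[, 3]       # anti-correlated pair
  fc <- window_fc(b)
  expect_equal(fc[1, 2], 1)
  expect_equal(fc[3, 4], -1)
  expect_true(isSymmetric(fc, tol = 1e-12))
  expect_equal(diag(fc), rep(1, 5), ignore_attr = TRUE)

  # naive two-pass covariance/normalization oracle
  centred <- sweep(b, 2, colMeans(b))
  cov2 <- crossprod(centred) / (nrow(b) - 1)
  oracle <- cov2 / sqrt(outer(diag(cov2), diag(cov2)))
  expect_equal(fc, oracle, tolerance = 1e-12, ignore_attr = TRUE)

  b[, 5] <- 3
  expect_error(window_fc(b), "zero-variance")
})

test_that("nodal/intra/inter variability match loop-based oracles to 1e-12", {
  part <- tiny_partition()
  m <- n_nodes(part)
  for (case in 1:6) {
    stack <- random_stack(m, n_win = sample(3:6, 1), seed = 100 + case)
    v <- nodal_variability(stack)
    for (k in c(1, 5, m)) {
      expect_equal(v[k], oracle_nodal(stack, k), tolerance = 1e-12)
    }
    for (mod in c("A", "C")) {
      expect_equal(as.numeric(intra_network_variability(stack, part, mod)),
                   oracle_intra(stack, part, mod), tolerance = 1e-12)
    }
    expect_equal(as.numeric(inter_network_variability(stack, part, "A", "B")),
                 oracle_inter(stack, part, "A", "B"), tolerance = 1e-12)
    expect_equal(as.numeric(inter_network_variability(stack, part, "B", "C")),
                 oracle_inter(stack, part, "B", "C"), tolerance = 1e-12)
  }
})

test_that("intra over the whole graph matches the oracle", {
  whole <- network_partition(data.frame(node_index = 1:4,
                                        module = c("G", "G", "G", "H")))
  # module G = 3 of 4 nodes; also test a one-module-dominant layout
  stack <- random_stack(4, n_win = 3, seed = 9)
  expect_equal(as.numeric(intra_network_variability(stack, whole, "G")),
               oracle_intra(stack, whole, "G"), tolerance = 1e-12)
})

test_that("identical windows give V = 0 and anti-correlated profiles give V = 2", {
  part <- tiny_partition()
  m <- n_nodes(part)
  one <- random_stack(m, 1, seed = 3)$windows[, , 1]
  stack <- structure(list(subject_id = "s", window_length = NA_integer_,
                          fisher_z = FALSE,
                          windows = array(rep(one, 4), c(m, m, 4))),
                     class = "fc_stack")
  expect_equal(unname(nodal_variability(stack)), rep(0, m),
               tolerance = 1e-12)
  expect_equal(as.numeric(intra_network_variability(stack, part, "A")), 0,
               tolerance = 1e-12)
  expect_equal(as.numeric(inter_network_variability(stack, part, "A", "B")),
               0, tolerance = 1e-12)

  # two windows whose node-1 profiles are exact mirrors: corr = -1, V = 2
  w1 <- diag(4)
  w1[1, 2:4] <- c(0.1, 0.2, 0.3)
  w1[2:4, 1] <- c(0.1, 0.2, 0.3)
  w2 <- diag(4)
  w2[1, 2:4] <- c(0.3, 0.2, 0.1)
  w2[2:4, 1] <- c(0.3, 0.2, 0.1)
  st2 <- structure(list(subject_id = "s", window_length = NA_integer_,
                        fisher_z = FALSE,
                        windows = array(c(w1, w2), c(4, 4, 2))),
                   class = "fc_stack")
  expect_equal(nodal_variability(st2)[1], 2, tolerance = 1e-12)
})

test_that("variability is invariant to positive affine node rescaling", {
  part <- tiny_partition()
  m <- n_nodes(part)
  set.seed(11)
  x <- matrix(rnorm(80 * m), 80, m)
  v1 <- variability_set(x, part, 20)
  y <- x
  y[, 3] <- 5.7 * x[, 3] + 2.2
  y[, 7] <- 0.01 * x[, 7] - 40
  v2 <- variability_set(y, part, 20)
  expect_equal(v1$nodal, v2$nodal, tolerance = 1e-10)
  expect_equal(v1$module_matrix, v2$module_matrix, tolerance = 1e-10)
})

test_that("pair averaging uses exactly N(N-1)/2 window pairs", {
  part <- tiny_partition()
  m <- n_nodes(part)
  for (n_win in 2:6) {
    stack <- random_stack(m, n_win, seed = 200 + n_win)
    # explicit enumeration for node 2
    rs <- c()
    for (i in seq_len(n_win - 1)) for (j in (i + 1):n_win) {
      rs <- c(rs, stats::cor(stack$windows[2, -2, i],
                             stack$windows[2, -2, j]))
    }
    expect_length(rs, n_win * (n_win - 1) / 2)
    expect_equal(nodal_variability(stack)[2], 1 - mean(rs),
                 tolerance = 1e-12)
  }
})

test_that("tiled periodic series gives exactly zero variability everywhere", {
  part <- tiny_partition()
  m <- n_nodes(part)
  set.seed(4)
  block <- matrix(rnorm(20 * m), 20, m)
  tiled <- do.call(rbind, rep(list(block), 10))
  vs <- variability_set(tiled, part, 20)
  expect_equal(unname(vs$nodal), rep(0, m), tolerance = 1e-10)
  expect_equal(unname(as.vector(vs$module_matrix)),
               rep(0, length(vs$module_matrix)), tolerance = 1e-10)
})

test_that("all variability values stay in [0, 2] on random and simulated data", {
  part <- tiny_partition()
  for (seed in 1:5) {
    stack <- random_stack(n_nodes(part), 5, seed = 300 + seed)
    v <- nodal_variability(stack)
    expect_true(all(v >= 0 & v <= 2))
  }
  spec <- tiny_spec(n_states = 1)
  subj <- simulate_subject(spec, "control", seed = 5)
  vs <- variability_set(subj$series, spec$partition, 20)
  expect_true(all(vs$nodal >= 0 & vs$nodal <= 2))
  expect_true(all(vs$module_matrix >= 0 & vs$module_matrix <= 2))
  expect_gt(mean(vs$nodal), 0)
})

test_that("inter-network variability is symmetric and rejects A = A", {
  part <- tiny_partition()
  stack <- random_stack(n_nodes(part), 4, seed = 17)
  ab <- inter_network_variability(stack, part, "A", "B")
  ba <- inter_network_variability(stack, part, "B", "A")
  expect_identical(as.numeric(ab), as.numeric(ba))
  expect_error(inter_network_variability(stack, part, "A", "A"),
               "intra_network_variability")
  expect_error(intra_network_variability(
    stack, network_partition(data.frame(node_index = 1:11,
                                        module = rep(c("A", "B"), c(2, 9)))),
    "A"), ">= 3")
})

test_that("degenerate profiles yield NA with a diagnostic, not a crash", {
  part <- tiny_partition()
  m <- n_nodes(part)
  stack <- random_stack(m, 3, seed = 23)
  stack$windows[1, -1, 2] <- 0.5   # node 1 profile constant in window 2
  stack$windows[-1, 1, 2] <- 0.5
  v <- nodal_variability(stack)
  expect_true(is.na(v[1]))
  expect_equal(attr(v, "degenerate_nodes"), 1L)
  expect_true(all(!is.na(v[-1])))
})

test_that("averaging over lengths follows the elementwise-mean rule", {
  part <- tiny_partition()
  set.seed(31)
  x <- matrix(rnorm(120 * n_nodes(part)), 120, n_nodes(part))
  s1 <- variability_set(x, part, 10)
  s2 <- variability_set(x, part, 12)
  s3 <- variability_set(x, part, 20)

  same <- average_over_lengths(list(s1, s1))
  expect_equal(same$nodal, s1$nodal, tolerance = 1e-12)

  avg <- average_over_lengths(list(s1, s2, s3))
  # per-entry loop oracle
  for (k in c(1, 6, 11)) {
    expect_equal(unname(avg$nodal[k]),
                 mean(c(s1$nodal[k], s2$nodal[k], s3$nodal[k])),
                 tolerance = 1e-12)
  }
  expect_equal(avg$module_matrix["A", "B"],
               mean(c(s1$module_matrix["A", "B"], s2$module_matrix["A", "B"],
                      s3$module_matrix["A", "B"])), tolerance = 1e-12)

  # one missing length -> mean of the present ones; two missing -> NA
  s2na <- s2; s2na$nodal[4] <- NA
  s3na <- s3; s3na$nodal[4] <- NA
  one_missing <- average_over_lengths(list(s1, s2na, s3))
  expect_equal(unname(one_missing$nodal[4]),
               mean(c(s1$nodal[4], s3$nodal[4])), tolerance = 1e-12)
  two_missing <- average_over_lengths(list(s1, s2na, s3na))
  expect_true(is.na(two_missing$nodal[4]))
})

test_that("window-length sweep reports unit self-correlation and symmetry", {
  part <- tiny_partition()
  set.seed(37)
  x <- subject_ts(matrix(rnorm(120 * n_nodes(part)), 120, n_nodes(part)))
  sw <- window_length_sweep(x, part, lengths = c(20, 20))
  expect_equal(unname(sw$cor_nodal), matrix(1, 2, 2), tolerance = 1e-12)

  sw2 <- window_length_sweep(x, part, lengths = c(10, 15, 20))
  expect_equal(sw2$cor_nodal, t(sw2$cor_nodal))
  expect_equal(unname(diag(sw2$cor_nodal)), rep(1, 3), tolerance = 1e-12)
  expect_equal(sw2$cor_module, t(sw2$cor_module))
  expect_true(all(sw2$cor_nodal >= -1 & sw2$cor_nodal <= 1))
  expect_identical(sweep_min_correlation(sw2),
                   min(sw2$cor_nodal[upper.tri(sw2$cor_nodal)]))
})

test_that("V_k estimates stabilize as the number of windows grows", {
  part <- tiny_partition()
  m <- n_nodes(part)
  spec <- tiny_spec(n_states = 1, amp_base = 0, amp_target = 0,
                    n_volumes = 200)
  sds <- sapply(c(2, 5, 10), function(n_win) {
    reps <- sapply(1:60, function(r) {
      subj <- simulate_subject(spec, "control", seed = 7000 + 17 * r)
      stack <- fc_window_stack(subj$series$data[1:(n_win * 20), ], 20)
      nodal_variability(stack)[1]
    })
    stats::sd(reps)
  })
  expect_true(sds[2] < sds[1])
  expect_true(sds[3] < sds[2])
})
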