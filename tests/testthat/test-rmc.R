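sim3 <- synth_spectrum_matrix(20, default_prototypes(3),
                              additive_noise_sd = 50, seed = 14)
S3r <- restrict_matrix(sim3$matrix)

test_that("masking hides the requested bins of one row only", {
  mk <- apply_mask(S3r, 4, 0.3, pattern = "band")
  expect_equal(sum(!mk$known[4, ]), round(0.3 * ncol(S3r$rows)))
  expect_true(all(mk$known[-4, ]))

  hf_bins <- which(S3r$freqs >= 0.15 & S3r$freqs <= 0.4)
  mk70 <- apply_mask(S3r, 4, 0.62, pattern = "band")
  hidden <- which(!mk70$known[4, ])
  expect_true(all(diff(hidden) == 1))          # contiguous block
  expect_gt(length(intersect(hidden, hf_bins)) / length(hidden), 0.9)

  r1 <- apply_mask(S3r, 2, 0.4, pattern = "random", seed = 5)
  r2 <- apply_mask(S3r, 2, 0.4, pattern = "random", seed = 5)
  expect_identical(r1$known, r2$known)
  r3 <- apply_mask(S3r, 2, 0.4, pattern = "random", seed = 6)
  expect_false(identical(r1$known, r3$known))

  expect_error(apply_mask(S3r, 2, 0), "ratio")
  expect_error(apply_mask(S3r, 2, 0.001), "none or all")
})

test_that("modelled correlation behaves like Pearson on the known bins", {
  grid <- full_grid()
  m1 <- spectrum_model(list(gaussian_component(1, 0.1, 0.02),
                            gaussian_component(0.5, 0.25, 0.03)))
  idx <- seq(10, 100, by = 2)
  expect_equal(modeled_correlation(m1, m1, grid, idx), 1)

  # positively scaled model correlates perfectly
  m2 <- spectrum_model(list(gaussian_component(3, 0.1, 0.02),
                            gaussian_component(1.5, 0.25, 0.03)))
  expect_equal(modeled_correlation(m1, m2, grid, idx), 1, tolerance = 1e-12)

  # direct-formula oracle on 5 points
  m3 <- spectrum_model(list(gaussian_component(0.8, 0.12, 0.03)))
  pts <- c(20, 25, 30, 35, 40)
  a <- eval_model(m1, grid)[pts]
  b <- eval_model(m3, grid)[pts]
  hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(modeled_correlation(m1, m3, grid, pts), hand, tolerance = 1e-12)

  expect_error(modeled_correlation(m1, m1, grid, 1:2), "3 known bins")
})

test_that("top-K selection sorts descending with stable tie-breaks", {
  expect_equal(select_top_k(c(0.2, 0.9, 0.5), 1), 2L)
  expect_setequal(select_top_k(c(0.2, 0.9, 0.5), 3), 1:3)
  expect_equal(select_top_k(c(0.5, 0.5, 0.1), 1), 1L)
  expect_equal(select_top_k(c(0.5, 0.5, 0.1), 2), c(1L, 2L))
  expect_error(select_top_k(c(0.1, 0.2), 3), "between")
})

test_that("the refined matrix stacks the target first with a row-confined mask", {
  mk <- apply_mask(S3r, 5, 0.3, pattern = "band")
  ref <- build_refined_matrix(S3r, mk, 5, c(9, 2, 17))
  expect_equal(nrow(ref$S_ref), 4)
  expect_equal(ref$S_ref[1, ], S3r$rows[5, ])
  expect_equal(ref$row_map, c(5, 9, 2, 17))
  expect_true(all(ref$mask_ref$known[-1, ]))
  expect_equal(ref$mask_ref$known[1, ], mk$known[5, ])
  expect_error(build_refined_matrix(S3r, mk, 5, c(5, 2)), "own donor")
})

test_that("an exact duplicate row drives near-perfect HF recovery", {
  S <- S3r$rows
  S[8, ] <- S[3, ]                     # duplicate of the target
  mk <- apply_mask(S, 3, 0.3, pattern = "band", freqs = S3r$freqs)
  hid <- which(!mk$known[3, ])
  r <- rmc_estimate(S, mk, 3, K = 3, freqs = S3r$freqs)
  expect_true(8 %in% r$selection$selected)
  expect_lt(rel_frob(r$estimate[hid], S[3, hid]), 1e-2)
})

test_that("K = n_rows - 1 reduces the refinement to full-matrix completion", {
  mk <- apply_mask(S3r, 6, 0.3, pattern = "band")
  r <- rmc_estimate(S3r, mk, 6, K = nrow(S3r$rows) - 1)
  full <- complete_matrix(S3r$rows, mk)
  hid <- which(!mk$known[6, ])
  expect_equal(r$estimate[hid], full$X[6, hid], tolerance = 1e-9)
})

test_that("observed bins of the target row are never altered", {
  for (seed in c(21, 22)) {
    sim <- synth_spectrum_matrix(15, default_prototypes(3),
                                 additive_noise_sd = 200, seed = seed)
    Sr <- restrict_matrix(sim$matrix)
    mk <- apply_mask(Sr, 2, 0.4, pattern = "random", seed = seed)
    r <- rmc_estimate(Sr, mk, 2, K = 5)
    known_idx <- which(mk$known[2, ])
    expect_identical(r$estimate[known_idx], Sr$rows[2, known_idx])
  }
})

test_that("rmc_estimate validates its preconditions", {
  mk <- apply_mask(S3r, 4, 0.3, pattern = "band")
  expect_error(rmc_estimate(S3r, mk, 4, K = 0), "K")
  expect_error(rmc_estimate(S3r, mk, 4, K = 20), "K")
  full <- observation_mask(matrix(TRUE, 20, ncol(S3r$rows)))
  expect_error(rmc_estimate(S3r, full, 4), "no hidden bins")
})

test_that("NRMSE matches hand-computed values and is scale invariant", {
  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3), 1:3), 0)
  expect_equal(nrmse(c(1, 2, 4), c(1, 2, 3), 1:3), sqrt(1 / 3), tolerance = 1e-12)
  # estimating every hidden bin by the truth's mean gives sqrt((N-1)/N)
  set.seed(6)
  truth <- rnorm(100)
  est <- rep(mean(truth), 100)
  expect_equal(nrmse(est, truth, 1:100), sqrt(99 / 100), tolerance = 1e-12)
  expect_equal(nrmse(7.3 * c(1, 2, 4), 7.3 * c(1, 2, 3), 1:3),
               nrmse(c(1, 2, 4), c(1, 2, 3), 1:3), tolerance = 1e-12)
  expect_error(nrmse(1, 1, 1), "2 hidden")
  expect_error(nrmse(c(1, 2), c(3, 3), 1:2), "zero variance")
})

test_that("sweeping K is deterministic and reports the argmin", {
  mk <- apply_mask(S3r, 7, 0.3, pattern = "band")
  hid <- which(!mk$known[7, ])
  sw1 <- sweep_k(S3r, mk, 7, c(3, 9, 19))
  sw2 <- sweep_k(S3r, mk, 7, c(3, 9, 19))
  expect_identical(sw1, sw2)
  expect_lte(min(sw1$table$nrmse), sw1$table$nrmse[sw1$table$K == 19])

  single <- sweep_k(S3r, mk, 7, 9)
  direct <- rmc_estimate(S3r, mk, 7, K = 9)
  expect_equal(single$table$nrmse, nrmse(direct$estimate, S3r$rows[7, ], hid))
  expect_equal(single$best_k, 9)
})

test_that("donor selection stays inside the target's cluster on near-pure data", {
  hits <- vapply(1:5, function(seed) {
    sim <- synth_spectrum_matrix(30, default_prototypes(3),
                                 dirichlet_alpha = 0.05,
                                 additive_noise_sd = 50, seed = 300 + seed)
    Sr <- restrict_matrix(sim$matrix)
    cl <- apply(sim$weights, 1, which.max)
    tgt <- which(cl == 1)[1]
    mk <- apply_mask(Sr, tgt, 0.3, pattern = "band")
    r <- rmc_estimate(Sr, mk, tgt, K = 5)
    mean(cl[r$selection$selected] == cl[tgt])
  }, numeric(1))
  expect_gte(stats::median(hits), 0.8)
})

test_that("the benchmark sweep emits one row per cell and summarises", {
  spec <- list(target_row = 5, ratio = 0.3, pattern = "band")
  b <- benchmark_methods(S3r, list(spec), methods = "rmc", seeds = 1L, K = 5)
  expect_equal(nrow(b$runs), 1)
  expect_equal(b$runs$method, "rmc")
  expect_true(is.finite(b$runs$nrmse))
  expect_equal(nrow(b$summary), 1)

  # results table round-trips through delimited text
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(b$runs, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.table(tf, header = TRUE, sep = "\t")
  expect_equal(back$nrmse, b$runs$nrmse, tolerance = 1e-12)
  expect_equal(back$method, b$runs$method)
  unlink(tf)
})
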