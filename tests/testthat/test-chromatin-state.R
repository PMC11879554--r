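# Binarization against a Poisson tail oracle, Baum-Welch parameter recovery,
# posterior decoding and state-feature enrichment.

toy_track <- function(x, lib = sum(x)) binned_track(list(chr1 = x),
                                                    library_size = lib)

test_that("binarization matches the Poisson-tail oracle", {
  # control gives lambda = 2 everywhere (equal library sizes)
  ctrl <- toy_track(rep(2L, 100), lib = 1000)
  x <- rep(2L, 100); x[1] <- 10L; x[2] <- 9L
  mark <- toy_track(x, lib = 1000)
  calls <- binarize_bins(mark, ctrl)
  oracle_tail <- function(count, lambda) 1 - sum(dpois(0:(count - 1), lambda))
  expect_lt(oracle_tail(10, 2), 1e-4)
  expect_gt(oracle_tail(9, 2), 1e-4)
  expect_equal(calls[1], 1L)
  expect_equal(calls[2], 0L)
  expect_true(all(calls[-(1:2)] == 0L))

  expect_true(all(binarize_bins(toy_track(rep(0L, 50), lib = 1)) == 0L))

  # doubling counts and lambda together changes calls only up to the
  # discreteness of the Poisson tail; both directions agree with the oracle
  set.seed(3)
  cx <- rpois(500, 3) + 1L
  mx <- as.integer(rpois(500, 4) + rbinom(500, 1, 0.05) * 30L)
  m1 <- toy_track(mx, lib = 1e4); c1 <- toy_track(cx, lib = 1e4)
  m2 <- toy_track(2L * mx, lib = 2e4); c2 <- toy_track(2L * cx, lib = 2e4)
  for (pair in list(list(m1, c1), list(m2, c2))) {
    got <- binarize_bins(pair[[1]], pair[[2]])
    lam <- pmax(unlist(pair[[2]]$counts) *
                  pair[[1]]$library_size / pair[[2]]$library_size,
                mean(unlist(pair[[2]]$counts) *
                       pair[[1]]$library_size / pair[[2]]$library_size))
    exp_call <- as.integer(mapply(function(k, l)
      k > 0 && oracle_tail(k, l) < 1e-4, unlist(pair[[1]]$counts), lam))
    expect_identical(got, exp_call)
  }
  expect_error(binarize_bins(toy_track(1:10), toy_track(1:5)), "grid")
})

test_that("a single-state fit is the closed-form column mean", {
  set.seed(5)
  X <- matrix(rbinom(300, 1, 0.3), 100, 3,
              dimnames = list(NULL, c("m1", "m2", "m3")))
  bm <- binary_chromatin_matrix(X, data.frame(chrom = "chr1",
                                              start = 0:99 * 200,
                                              end = 1:100 * 200))
  fit <- fit_chromatin_hmm(bm, K = 1)
  expect_equal(unname(fit$emission[1, ]), unname(colMeans(X)))
  seg <- decode_states(fit, bm)
  expect_true(all(seg$bins$state == 1))
  expect_equal(seg$coverage, 1)
  expect_error(fit_chromatin_hmm(bm, K = 200), "exceeds")
})

test_that("EM recovers a well-separated generating model", {
  em <- rbind(c(.9, .9, .1, .1, .1),
              c(.1, .1, .9, .9, .1),
              c(.1, .9, .1, .9, .9),
              c(.05, .05, .05, .05, .05))
  colnames(em) <- paste0("m", 1:5)
  tr <- matrix(0.02, 4, 4); diag(tr) <- 0.94
  mod <- chromatin_state_model(em, tr, rep(0.25, 4))
  sm <- sample_chromatin_matrix(mod, 4000, n_chrom = 2, seed = 5)
  fit <- fit_chromatin_hmm(sm$matrix, 4, seed = 3)
  m <- match_states(fit$emission, em)
  expect_lte(m$linf, 0.05)
  # EM guarantee: non-decreasing log-likelihood
  expect_true(all(diff(fit$log_likelihood_trace) >= -1e-8))
  # row-stochasticity after EM
  expect_equal(rowSums(fit$transition), rep(1, 4), tolerance = 1e-9)
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)
  # planted state coverage recovered within 2 percentage points
  seg <- decode_states(fit, sm$matrix)
  truth_cov <- tabulate(sm$states, 4) / length(sm$states)
  expect_lte(max(abs(sort(seg$coverage) - sort(truth_cov))), 0.02)
})

test_that("decoding collapses to the generating path for 0/1 emissions", {
  em <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  colnames(em) <- paste0("m", 1:3)
  tr <- matrix(0.1, 3, 3); diag(tr) <- 0.8
  mod <- chromatin_state_model(em, tr, rep(1 / 3, 3))
  sm <- sample_chromatin_matrix(mod, 500, seed = 9)
  seg <- decode_states(mod, sm$matrix)
  expect_identical(seg$bins$state, sm$states)
  # posterior rows are distributions
  expect_equal(rowSums(seg$posterior), rep(1, 500), tolerance = 1e-9)

  # uniform model: every bin ties, resolved to state 1
  uni <- chromatin_state_model(matrix(0.5, 2, 3,
                                      dimnames = list(NULL, paste0("m", 1:3))),
                               matrix(0.5, 2, 2), c(0.5, 0.5))
  seg_u <- decode_states(uni, sm$matrix)
  expect_true(all(seg_u$bins$state == 1))
  expect_error(decode_states(mod, binary_chromatin_matrix(
    matrix(0L, 5, 2, dimnames = list(NULL, c("x", "y"))),
    data.frame(chrom = "c", start = 0:4 * 200, end = 1:5 * 200))), "mark")
})

test_that("state-feature enrichment follows its defining ratio", {
  bins <- data.frame(chrom = "chr1", start = 0:999 * 200, end = 1:1000 * 200)
  seg <- structure(list(bins = cbind(bins,
                                     state = rep(c(1, 2), c(100, 900))),
                        coverage = c(0.1, 0.9), K = 2),
                   class = "chromatin_segmentation")
  feat <- data.frame(chrom = "chr1", start = 0, end = 100 * 200)
  fe <- state_feature_enrichment(seg, feat, genome_size = 1000 * 200)
  expect_equal(fe$fold_enrichment[1], 10)
  expect_equal(fe$fold_enrichment[2], 0)
  whole <- data.frame(chrom = "chr1", start = 0, end = 1000 * 200)
  fe2 <- state_feature_enrichment(seg, whole, genome_size = 1000 * 200)
  expect_equal(fe2$fold_enrichment, c(1, 1))
})

test_that("the state-count sweep reports likelihood and BIC per K", {
  em <- rbind(c(.9, .1, .1), c(.1, .9, .9))
  colnames(em) <- paste0("m", 1:3)
  mod <- chromatin_state_model(em, matrix(c(.9, .1, .1, .9), 2, byrow = TRUE),
                               c(.5, .5))
  sm <- sample_chromatin_matrix(mod, 800, seed = 2)
  sw <- sweep_state_count(sm$matrix, K_values = 2:4, seed = 1,
                          max_iter = 20, tol = 1e-2)
  expect_equal(sw$K, 2:4)
  expect_true(all(is.finite(sw$log_likelihood)))
  expect_true(all(is.finite(sw$BIC)))
})
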