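#' Chromatin-state model (multivariate Bernoulli HMM)
#'
#' A K-state hidden Markov model over binary mark vectors: each state emits
#' each histone mark independently with a state-specific presence
#' probability. This is the model family used to segment genomes into
#' chromatin states from binarized 200-bp ChIP bins.
#'
#' @param emission K x M matrix of P(mark present | state); column names are
#'   mark names
#' @param transition K x K row-stochastic matrix
#' @param initial length-K probability vector
#' @param log_likelihood_trace optional per-iteration log-likelihoods from EM
#' @return object of class \code{chromatin_state_model}
#' @export
chromatin_state_model <- function(emission, transition, initial,
                                  log_likelihood_trace = numeric(0)) {
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  K <- nrow(emission)
  stopifnot(nrow(transition) == K, ncol(transition) == K,
            length(initial) == K)
  if (any(emission < 0 | emission > 1))
    stop("emission probabilities must lie in [0,1]")
  if (any(abs(rowSums(transition) - 1) > 1e-9))
    stop("transition rows must sum to 1")
  if (abs(sum(initial) - 1) > 1e-9)
    stop("initial probabilities must sum to 1")
  structure(list(K = K,
                 mark_names = colnames(emission),
                 emission = emission,
                 transition = transition,
                 initial = as.numeric(initial),
                 log_likelihood_trace = log_likelihood_trace),
            class = "chromatin_state_model")
}

#' @export
print.chromatin_state_model <- function(x, ...) {
  cat(sprintf("chromatin_state_model: %d states x %d marks\n",
              x$K, ncol(x$emission)))
  if (length(x$log_likelihood_trace))
    cat(sprintf("  EM iterations: %d, final logLik %.3f\n",
                length(x$log_likelihood_trace),
                tail(x$log_likelihood_trace, 1)))
  invisible(x)
}

#' Binary chromatin matrix
#'
#' Bins x marks presence/absence calls with their genomic coordinates.
#'
#' @param matrix integer/logical bins x marks matrix over {0,1}
#' @param bins data.frame with columns chrom, start, end (0-based half-open)
#' @return object of class \code{binary_chromatin_matrix}
#' @export
binary_chromatin_matrix <- function(matrix, bins) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "integer"
  if (any(!matrix %in% c(0L, 1L))) stop("matrix entries must be 0/1")
  stopifnot(nrow(bins) == nrow(matrix),
            all(c("chrom", "start", "end") %in% names(bins)))
  structure(list(matrix = matrix,
                 mark_names = colnames(matrix),
                 bins = as.data.frame(bins)),
            class = "binary_chromatin_matrix")
}

#' Binarize one mark track against a control
#'
#' A bin is called present when its count is improbably high under a Poisson
#' background: P(X >= count; lambda) < p_threshold. The expectation lambda is
#' the control count scaled to the mark's library size (floored at the
#' genome-wide mean of the scaled control so empty control bins cannot make
#' every read significant); without a control the global mean mark count is
#' used.
#'
#' @param mark,control \code{binned_track} objects on the same bin grid
#'   (control may be NULL)
#' @param p_threshold upper-tail probability cutoff
#' @return integer 0/1 vector over all bins (chromosomes concatenated in the
#'   track's chromosome order)
#' @export
binarize_bins <- function(mark, control = NULL, p_threshold = 1e-4) {
  x <- unlist(mark$counts, use.names = FALSE)
  if (!is.null(control)) {
    if (!identical(lapply(mark$counts, length), lapply(control$counts, length)))
      stop("mark and control tracks are on different bin grids")
    ctrl <- unlist(control$counts, use.names = FALSE)
    scale <- mark$library_size / control$library_size
    lambda <- ctrl * scale
    lambda <- pmax(lambda, mean(lambda))
  } else {
    lambda <- rep(mean(x), length(x))
  }
  # P(X >= x) = ppois(x - 1, lambda, lower.tail = FALSE)
  tail_p <- ppois(x - 1, lambda, lower.tail = FALSE)
  as.integer(x > 0 & tail_p < p_threshold)
}

#' Binarize a set of mark tracks into a binary chromatin matrix
#'
#' @param marks named list of \code{binned_track}s (one per mark)
#' @param control optional control \code{binned_track}
#' @param p_threshold see \code{\link{binarize_bins}}
#' @return \code{binary_chromatin_matrix}
#' @export
binarize_tracks <- function(marks, control = NULL, p_threshold = 1e-4) {
  stopifnot(length(marks) >= 1, !is.null(names(marks)))
  cols <- lapply(marks, binarize_bins, control = control,
                 p_threshold = p_threshold)
  m <- do.call(cbind, cols)
  colnames(m) <- names(marks)
  tr <- marks[[1]]
  bins <- do.call(rbind, lapply(names(tr$counts), function(ch) {
    n <- length(tr$counts[[ch]])
    data.frame(chrom = ch,
               start = (seq_len(n) - 1L) * tr$bin_width,
               end = seq_len(n) * tr$bin_width)
  }))
  binary_chromatin_matrix(m, bins)
}

## ---- Baum-Welch -----------------------------------------------------------

# per-bin emission probabilities for binary data: T x K
bernoulli_emission_prob <- function(X, emission) {
  e <- clamp(emission, 1e-6, 1 - 1e-6)
  # log P(x_t | state k) = sum_m x log e + (1-x) log(1-e)
  lb <- X %*% t(log(e)) + (1 - X) %*% t(log(1 - e))
  exp(lb)
}

# scaled forward-backward for one sequence; returns gamma, xi sums, logLik
forward_backward <- function(B, transition, initial) {
  Tn <- nrow(B); K <- ncol(B)
  alpha <- matrix(0, Tn, K)
  beta <- matrix(0, Tn, K)
  scale <- numeric(Tn)
  a <- initial * B[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% transition) * B[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta[Tn, ] <- 1
  for (t in (Tn - 1):1) {
    b <- transition %*% (B[t + 1, ] * beta[t + 1, ])
    beta[t, ] <- b / scale[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  # accumulated xi (K x K)
  xi <- matrix(0, K, K)
  for (t in seq_len(Tn - 1)) {
    m <- outer(alpha[t, ], B[t + 1, ] * beta[t + 1, ]) * transition
    xi <- xi + m / sum(m)
  }
  list(gamma = gamma, xi = xi, loglik = sum(log(scale)))
}

# kmeans++ seeding on binary rows, then Lloyd iterations via stats::kmeans
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(0, K, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  k <- 2
  while (k <= K) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[k, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[k, ], n, ncol(X),
                                       byrow = TRUE))^2))
    k <- k + 1
  }
  centers
}

#' Fit a chromatin-state HMM by Baum-Welch EM
#'
#' Emissions are independent Bernoulli per mark given the state.
#' Chromosomes are treated as independent observation sequences sharing one
#' parameter set. Emission probabilities are initialized from k-means++
#' cluster means of the binary mark vectors; transitions start near-uniform
#' with 0.9 self-transition.
#'
#' @param matrix a \code{binary_chromatin_matrix}
#' @param K number of states
#' @param seed RNG seed for initialization
#' @param max_iter,tol EM stopping rule: stop when the log-likelihood gain
#'   falls below \code{tol} or after \code{max_iter} iterations
#' @return a \code{chromatin_state_model} with \code{log_likelihood_trace}
#' @export
fit_chromatin_hmm <- function(matrix, K, seed = 1L, max_iter = 100L,
                              tol = 1e-4) {
  stopifnot(inherits(matrix, "binary_chromatin_matrix"))
  X <- matrix$matrix
  if (K < 1) stop("K must be >= 1")
  if (K > nrow(X)) stop("K exceeds the number of bins")
  storage.mode(X) <- "double"
  seqs <- split(seq_len(nrow(X)), factor(matrix$bins$chrom,
                                         levels = unique(matrix$bins$chrom)))
  set.seed(seed)
  if (K == 1) {
    emission <- rbind(colMeans(X))
    colnames(emission) <- matrix$mark_names
    B <- bernoulli_emission_prob(X, emission)
    ll <- sum(log(B))
    return(chromatin_state_model(emission, matrix(1, 1, 1), 1,
                                 log_likelihood_trace = ll))
  }
  km <- tryCatch(
    kmeans(X, centers = kmeanspp_centers(X, K), iter.max = 50),
    error = function(e) kmeans(jitter(X, amount = 1e-3), centers = K))
  emission <- clamp(km$centers, 0.01, 0.99)
  colnames(emission) <- matrix$mark_names
  transition <- matrix(0.1 / (K - 1), K, K)
  diag(transition) <- 0.9
  initial <- rep(1 / K, K)

  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    gsum <- matrix(0, K, ncol(X))        # sum_t gamma_tk * x_t
    gtot <- numeric(K)                   # sum_t gamma_tk
    xi <- matrix(0, K, K)
    gfrom <- numeric(K)                  # sum over t<Tn of gamma
    ginit <- numeric(K)
    ll <- 0
    for (s in seqs) {
      B <- bernoulli_emission_prob(X[s, , drop = FALSE], emission)
      fb <- forward_backward(B, transition, initial)
      ll <- ll + fb$loglik
      gsum <- gsum + t(fb$gamma) %*% X[s, , drop = FALSE]
      gtot <- gtot + colSums(fb$gamma)
      xi <- xi + fb$xi
      gfrom <- gfrom + colSums(fb$gamma[-length(s), , drop = FALSE])
      ginit <- ginit + fb$gamma[1, ]
    }
    trace <- c(trace, ll)
    emission <- clamp(gsum / gtot, 1e-6, 1 - 1e-6)
    colnames(emission) <- matrix$mark_names
    transition <- xi / pmax(gfrom, .Machine$double.xmin)
    transition <- transition / rowSums(transition)
    initial <- ginit / sum(ginit)
    if (iter > 1 && (trace[iter] - trace[iter - 1]) < tol) break
  }
  chromatin_state_model(emission, transition, initial,
                        log_likelihood_trace = trace)
}

#' Decode per-bin chromatin states
#'
#' Maximum-posterior (forward-backward) state per bin; ties resolved toward
#' the lowest state index. Also reports genome coverage per state.
#'
#' @param model a \code{chromatin_state_model}
#' @param matrix a \code{binary_chromatin_matrix} over the same marks
#' @return object of class \code{chromatin_segmentation}: list with
#'   \code{bins} (chrom/start/end/state), \code{coverage} (per-state genome
#'   fraction) and \code{posterior} (bins x K matrix)
#' @export
decode_states <- function(model, matrix) {
  stopifnot(inherits(model, "chromatin_state_model"),
            inherits(matrix, "binary_chromatin_matrix"))
  if (!identical(model$mark_names, matrix$mark_names))
    stop("model and matrix mark sets differ")
  X <- matrix$matrix
  storage.mode(X) <- "double"
  seqs <- split(seq_len(nrow(X)), factor(matrix$bins$chrom,
                                         levels = unique(matrix$bins$chrom)))
  post <- matrix(0, nrow(X), model$K)
  for (s in seqs) {
    B <- bernoulli_emission_prob(X[s, , drop = FALSE], model$emission)
    if (model$K == 1) {
      post[s, ] <- 1
    } else {
      fb <- forward_backward(B, model$transition, model$initial)
      post[s, ] <- fb$gamma
    }
  }
  state <- max.col(post, ties.method = "first")
  cov <- tabulate(state, nbins = model$K) / length(state)
  structure(list(bins = cbind(matrix$bins, state = state),
                 coverage = cov,
                 posterior = post,
                 K = model$K),
            class = "chromatin_segmentation")
}

#' Per-state fold enrichment over a feature set
#'
#' FE(state) = (overlap(state, feature) / coverage(state)) /
#'             (coverage(feature) / genome_size), all in bp.
#'
#' @param seg a \code{chromatin_segmentation}
#' @param features data.frame chrom/start/end (0-based half-open)
#' @param genome_size total genome length in bp
#' @return data.frame with state, state_bp, overlap_bp, fold_enrichment
#'   (NA for empty states)
#' @export
state_feature_enrichment <- function(seg, features, genome_size) {
  stopifnot(inherits(seg, "chromatin_segmentation"))
  b <- seg$bins
  fgr <- GenomicRanges::GRanges(features$chrom,
                                IRanges::IRanges(features$start + 1L,
                                                 features$end))
  fgr <- GenomicRanges::reduce(fgr)
  bgr <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1L, b$end))
  ov <- GenomicRanges::findOverlaps(bgr, fgr)
  ow <- numeric(nrow(b))
  if (length(ov)) {
    w <- IRanges::width(IRanges::pintersect(bgr[S4Vectors::queryHits(ov)],
                                            fgr[S4Vectors::subjectHits(ov)]))
    ow_by <- tapply(w, S4Vectors::queryHits(ov), sum)
    ow[as.integer(names(ow_by))] <- ow_by
  }
  bin_bp <- b$end - b$start
  state_bp <- tapply(bin_bp, factor(b$state, levels = seq_len(seg$K)), sum,
                     default = 0)
  overlap_bp <- tapply(ow, factor(b$state, levels = seq_len(seg$K)), sum,
                       default = 0)
  feat_bp <- sum(IRanges::width(fgr))
  fe <- ifelse(state_bp > 0,
               (overlap_bp / state_bp) / (feat_bp / genome_size),
               NA_real_)
  data.frame(state = seq_len(seg$K),
             state_bp = as.numeric(state_bp),
             overlap_bp = as.numeric(overlap_bp),
             fold_enrichment = as.numeric(fe))
}

#' Sweep the number of chromatin states
#'
#' Fits the HMM for each candidate K and reports log-likelihood and BIC;
#' model choice is left to the analyst (as in segmenting real epigenomes,
#' where the state count is picked by interpretability).
#'
#' @inheritParams fit_chromatin_hmm
#' @param K_values candidate state counts
#' @return data.frame with K, log_likelihood, n_parameters, BIC
#' @export
sweep_state_count <- function(matrix, K_values = 10:20, seed = 1L,
                              max_iter = 50L, tol = 1e-3) {
  n <- nrow(matrix$matrix); M <- ncol(matrix$matrix)
  res <- lapply(K_values, function(K) {
    fit <- fit_chromatin_hmm(matrix, K, seed = seed, max_iter = max_iter,
                             tol = tol)
    ll <- tail(fit$log_likelihood_trace, 1)
    npar <- K * M + K * (K - 1) + (K - 1)
    data.frame(K = K, log_likelihood = ll, n_parameters = npar,
               BIC = -2 * ll + npar * log(n))
  })
  do.call(rbind, res)
}

#' Sample a state path and binary emissions from a chromatin-state model
#'
#' Generator-side counterpart of \code{\link{fit_chromatin_hmm}}, used to
#' create matrices with known truth.
#'
#' @param model a \code{chromatin_state_model}
#' @param n_bins bins per chromosome
#' @param n_chrom number of independent chromosome sequences
#' @param seed RNG seed
#' @return list with \code{matrix} (a \code{binary_chromatin_matrix}) and
#'   \code{states} (integer truth path)
#' @export
sample_chromatin_matrix <- function(model, n_bins, n_chrom = 1L, seed = 1L) {
  set.seed(seed)
  K <- model$K; M <- ncol(model$emission)
  all_states <- integer(0)
  rows <- list()
  bins <- list()
  for (ch in seq_len(n_chrom)) {
    s <- integer(n_bins)
    s[1] <- sample.int(K, 1, prob = model$initial)
    for (t in seq_len(n_bins - 1))
      s[t + 1] <- sample.int(K, 1, prob = model$transition[s[t], ])
    X <- matrix(rbinom(n_bins * M, 1, model$emission[s, ]), n_bins, M)
    colnames(X) <- model$mark_names
    rows[[ch]] <- X
    all_states <- c(all_states, s)
    bins[[ch]] <- data.frame(chrom = sprintf("chr%d", ch),
                             start = (seq_len(n_bins) - 1L) * 200L,
                             end = seq_len(n_bins) * 200L)
  }
  list(matrix = binary_chromatin_matrix(do.call(rbind, rows),
                                        do.call(rbind, bins)),
       states = all_states)
}

#' Match fitted states to reference states
#'
#' Finds the state permutation minimizing the L-infinity distance between a
#' fitted and a reference emission matrix (exhaustive over permutations;
#' intended for small K in recovery checks).
#'
#' @param fitted,reference emission matrices with equal dimensions
#' @return list with \code{perm} (fitted row order) and \code{linf} error
#' @export
match_states <- function(fitted, reference) {
  K <- nrow(reference)
  stopifnot(nrow(fitted) == K)
  perms <- permutations_of(K)
  best <- NULL; best_err <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    err <- max(abs(fitted[p, , drop = FALSE] - reference))
    if (err < best_err) { best_err <- err; best <- p }
  }
  list(perm = best, linf = best_err)
}

# all permutations of 1..n as rows (n small)
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
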