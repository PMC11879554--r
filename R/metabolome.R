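## Differential metabolite calling: PLS-DA VIP scores (NIPALS) combined with
## fold-change and Welch-test thresholds (VIP >= 1, |log2FC| >= 1, P < 0.05).

#' Build a metabolite table object from intensities and group labels
#'
#' Zero intensities are imputed to half the metabolite's minimum positive
#' value (flagged); constant metabolites are flagged for exclusion from the
#' PLS model.
#'
#' @param table data.frame with a metabolite column and sample columns
#' @param groups named character vector: sample -> group (two groups); NULL
#'   parses \code{group_replicate} column names
#' @return object of class \code{metabolite_table}
#' @export
metabolite_table <- function(table, groups = NULL) {
  samples <- setdiff(names(table), "metabolite")
  if (is.null(groups))
    groups <- stats::setNames(sub("_[^_]+$", "", samples), samples)
  groups <- groups[samples]
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need >= 2 replicates per group")
  m <- as.matrix(table[, samples])
  rownames(m) <- table$metabolite
  imputed <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    z <- m[i, ] <= 0
    if (any(z)) {
      posmin <- min(m[i, !z])
      m[i, z] <- posmin / 2
      imputed[i] <- TRUE
    }
  }
  structure(list(intensities = m, groups = groups, group_levels = lv,
                 imputed = stats::setNames(imputed, rownames(m))),
            class = "metabolite_table")
}

#' PLS-DA VIP scores by NIPALS
#'
#' Intensities are autoscaled (centered, unit variance) and regressed on the
#' centered two-group indicator with NIPALS PLS.
#' VIP_j = sqrt(p * sum_a(SSY_a w_aj^2) / sum_a SSY_a), so the VIPs of the
#' modeled metabolites always satisfy sum(VIP^2) = p. Zero-variance
#' metabolites are excluded with an NA score.
#'
#' @param mt a \code{\link{metabolite_table}}
#' @param n_components number of PLS components (default 2)
#' @return named VIP vector over all metabolites (NA for excluded ones)
#' @export
plsda_vip <- function(mt, n_components = 2L) {
  stopifnot(inherits(mt, "metabolite_table"))
  X0 <- t(mt$intensities)                   # samples x metabolites
  y <- as.numeric(mt$groups == mt$group_levels[1])
  n <- nrow(X0)
  if (n_components < 1 || n_components >= min(n, ncol(X0)))
    stop("n_components must be >= 1 and < min(samples, metabolites)")
  sds <- apply(X0, 2, sd)
  keep <- sds > 0
  X <- scale(X0[, keep, drop = FALSE])
  yv <- y - mean(y)
  if (all(yv == 0)) stop("groups are degenerate (identical labels)")
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  ssy <- numeric(n_components)
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(X, yv))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ssy <- ssy[seq_len(a - 1)]; W <- W[, seq_len(a - 1),
                                                        drop = FALSE]; break }
    w <- w / nw
    t_sc <- drop(X %*% w)
    tt <- sum(t_sc^2)
    p_load <- drop(crossprod(X, t_sc)) / tt
    q <- sum(yv * t_sc) / tt
    X <- X - tcrossprod(t_sc, p_load)
    yv <- yv - q * t_sc
    W[, a] <- w
    ssy[a] <- q^2 * tt
  }
  vip_kept <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  vip <- rep(NA_real_, length(keep))
  names(vip) <- colnames(X0)
  vip[keep] <- vip_kept
  vip
}

#' Call differentially accumulated metabolites
#'
#' log2fc = log2(mean group1 / mean group2); p from a two-sided Welch t-test
#' on log2 intensities. Status up requires log2fc >= 1, p < alpha and
#' VIP >= 1 (down symmetric).
#'
#' @param mt a \code{\link{metabolite_table}}
#' @param vip VIP vector from \code{\link{plsda_vip}} on the same table
#' @param alpha significance level
#' @return list with \code{calls} (metabolite, log2fc, p_value, vip, status,
#'   imputed) and \code{summary} (n_up, n_down, n_total)
#' @export
call_dams <- function(mt, vip, alpha = 0.05) {
  stopifnot(inherits(mt, "metabolite_table"))
  mets <- rownames(mt$intensities)
  if (!all(mets %in% names(vip))) stop("missing VIP for some metabolites")
  g1 <- mt$groups == mt$group_levels[1]
  m <- mt$intensities
  log2fc <- log2(rowMeans(m[, g1, drop = FALSE]) /
                   rowMeans(m[, !g1, drop = FALSE]))
  lg <- log2(m)
  p <- vapply(seq_len(nrow(m)), function(i) {
    x <- lg[i, g1]; y <- lg[i, !g1]
    if (sd(x) == 0 && sd(y) == 0)
      return(if (isTRUE(all.equal(mean(x), mean(y)))) 1 else 0)
    t.test(x, y)$p.value
  }, 0)
  v <- vip[mets]
  status <- rep("not_dam", length(mets))
  status[!is.na(v) & v >= 1 & p < alpha & log2fc >= 1] <- "up"
  status[!is.na(v) & v >= 1 & p < alpha & log2fc <= -1] <- "down"
  calls <- data.frame(metabolite = mets, log2fc = log2fc, p_value = p,
                      vip = v, status = status,
                      imputed = mt$imputed[mets], row.names = NULL)
  list(calls = calls,
       summary = c(n_up = sum(status == "up"),
                   n_down = sum(status == "down"),
                   n_total = length(mets)))
}
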