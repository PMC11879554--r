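## Co-expression modules: soft-threshold adjacency, topological overlap,
## average-linkage clustering with a static cut, size filter and eigengene
## merging, and module-trait correlation.

#' Scale-free topology fit of a connectivity distribution
#'
#' R-squared of the log10 frequency vs log10 connectivity regression over
#' equal-width connectivity bins (empty bins dropped).
#'
#' @param k per-gene connectivity (row sums of adjacency, diagonal excluded)
#' @param n_breaks histogram bins
#' @return R-squared in [0, 1] (NA if fewer than 3 populated bins)
#' @export
scale_free_fit <- function(k, n_breaks = 10L) {
  k <- k[k > 0]
  if (length(k) < 3) return(NA_real_)
  cuts <- cut(k, breaks = n_breaks)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(pk[ok]) ~ log10(dk[ok]))
  summary(fit)$r.squared
}

#' Unsigned adjacency from an expression matrix
#'
#' adjacency_ij = |Pearson cor|^power over samples; diagonal set to 0 for
#' connectivity computations.
#'
#' @param expr samples x genes numeric matrix
#' @param power soft-threshold exponent
#' @return genes x genes adjacency with zero diagonal
#' @export
adjacency_matrix <- function(expr, power) {
  a <- abs(cor(expr))^power
  diag(a) <- 0
  a
}

#' Pick the soft threshold
#'
#' Smallest candidate power whose scale-free topology fit exceeds
#' \code{fit_cut}; when none qualifies, the maximum candidate is returned
#' with a warning.
#'
#' @param expr samples x genes matrix (>= 4 samples)
#' @param candidate_powers candidate exponents (>= 2 values)
#' @param fit_cut fit threshold (default 0.85)
#' @return list with \code{power} and \code{fit_table} (power, r_squared,
#'   mean_k)
#' @export
pick_soft_threshold <- function(expr, candidate_powers = c(1:10, 12, 14, 16),
                                fit_cut = 0.85) {
  if (nrow(expr) < 4) stop("need >= 4 samples for stable correlations")
  if (length(candidate_powers) < 2) stop("need >= 2 candidate powers")
  candidate_powers <- sort(candidate_powers)
  r <- abs(cor(expr))
  diag(r) <- 0
  tab <- do.call(rbind, lapply(candidate_powers, function(p) {
    k <- rowSums(r^p)
    data.frame(power = p, r_squared = scale_free_fit(k), mean_k = mean(k))
  }))
  ok <- which(!is.na(tab$r_squared) & tab$r_squared > fit_cut)
  if (length(ok)) power <- tab$power[ok[1]] else {
    warning("no candidate power exceeds the fit threshold; using the maximum")
    power <- max(candidate_powers)
  }
  list(power = power, fit_table = tab)
}

#' Topological overlap matrix
#'
#' TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij) with
#' k the connectivity (row sums excluding the diagonal); TOM_ii = 1.
#'
#' @param adjacency symmetric matrix with entries in [0, 1]
#' @return TOM matrix
#' @export
tom_from_adjacency <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-10) stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency entries must lie in [0,1]")
  diag(a) <- 0
  k <- rowSums(a)
  L <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (L + a) / denom
  diag(tom) <- 1
  tom
}

# first-PC eigengene of a module, sign-anchored to the module mean profile
module_eigengene <- function(expr, genes) {
  sub <- scale(expr[, genes, drop = FALSE])
  sub[is.nan(sub)] <- 0
  pc <- prcomp(sub, center = FALSE, scale. = FALSE)
  e <- pc$x[, 1]
  if (cor(e, rowMeans(sub)) < 0) e <- -e
  e / sqrt(sum(e^2))
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering on 1 - TOM, cut at a static
#' height (default 0.95: on a 1 - TOM dissimilarity the uninformative merges
#' concentrate just below 1, so the cut must sit under them); clusters below
#' \code{min_size} go to "grey". Modules whose eigengenes are closer than
#' \code{merge_cut} in correlation distance are merged iteratively until
#' stable.
#'
#' @param tom topological overlap matrix (genes in columns of \code{expr})
#' @param expr samples x genes matrix used for eigengenes
#' @param min_size minimum module size (default 40)
#' @param merge_cut eigengene merge height, 1 - cor (default 0.15)
#' @param cut_height static tree-cut height on the 1 - TOM scale
#' @return list with \code{modules} (gene -> label, "grey" = unassigned),
#'   \code{eigengenes} (samples x modules matrix) and \code{tree}
#' @export
detect_modules <- function(tom, expr, min_size = 40L, merge_cut = 0.15,
                           cut_height = 0.95) {
  genes <- colnames(tom) %||% colnames(expr)
  diss <- 1 - tom
  tree <- hclust(as.dist(diss), method = "average")
  cl <- cutree(tree, h = cut_height)
  sizes <- table(cl)
  labels <- ifelse(cl %in% as.integer(names(sizes)[sizes >= min_size]),
                   paste0("M", cl), "grey")
  names(labels) <- genes
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(labels), "grey")
    if (length(mods) < 2) break
    eg <- sapply(mods, function(m)
      module_eigengene(expr, names(labels)[labels == m]))
    d <- 1 - cor(eg)
    diag(d) <- Inf
    if (min(d) >= merge_cut) break
    ix <- which(d == min(d), arr.ind = TRUE)[1, ]
    from <- mods[max(ix)]; to <- mods[min(ix)]
    labels[labels == from] <- to
  }
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) {
    warning("all genes unassigned (grey)")
    return(list(modules = labels,
                eigengenes = matrix(numeric(0), nrow(expr), 0),
                tree = tree))
  }
  # stable final names by size
  ord <- names(sort(table(labels[labels != "grey"]), decreasing = TRUE))
  newlab <- stats::setNames(paste0("module", seq_along(ord)), ord)
  labels[labels != "grey"] <- newlab[labels[labels != "grey"]]
  mods <- unname(newlab)
  eg <- sapply(mods, function(m)
    module_eigengene(expr, names(labels)[labels == m]))
  rownames(eg) <- rownames(expr)
  list(modules = labels, eigengenes = eg, tree = tree)
}

#' Correlate module eigengenes with a sample trait
#'
#' Pearson correlation with a t-distribution p-value on n - 2 degrees of
#' freedom.
#'
#' @param eigengenes samples x modules matrix (\code{\link{detect_modules}})
#' @param trait numeric trait per sample
#' @return data.frame module, r, p_value (undefined flag when the trait is
#'   constant)
#' @export
module_trait_correlation <- function(eigengenes, trait) {
  if (sd(trait) == 0)
    return(data.frame(module = colnames(eigengenes), r = NA_real_,
                      p_value = NA_real_, undefined = TRUE))
  n <- length(trait)
  rows <- lapply(colnames(eigengenes), function(m) {
    r <- cor(eigengenes[, m], trait)
    tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-15))
    data.frame(module = m, r = r,
               p_value = 2 * pt(-abs(tstat), df = n - 2),
               undefined = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
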