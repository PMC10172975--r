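#' Simple linear regression with Pearson correlation
#'
#' Least-squares slope and intercept, Pearson R, and the two-sided
#' regression p value from the t statistic with `n - 2` degrees of
#' freedom.
#'
#' @param xs,ys Numeric vectors of equal length (pairs with `NA` in
#'   either are dropped).
#' @return List of class `linregress` with `slope`, `intercept`, `r`,
#'   `p_value`, `n`.
#' @export
linregress <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  keep <- !is.na(xs) & !is.na(ys)
  x <- xs[keep]; y <- ys[keep]
  n <- length(x)
  if (n < 2) stop("degenerate: need at least 2 complete pairs")
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  syy <- sum((y - yb)^2)
  if (sxx == 0) stop("degenerate: zero variance in xs")
  if (syy == 0) stop("degenerate: zero variance in ys")
  sxy <- sum((x - xb) * (y - yb))
  slope <- sxy / sxx
  r <- sxy / sqrt(sxx * syy)
  p <- NA_real_
  if (n >= 3) {
    if (abs(r) >= 1) {
      p <- 0
    } else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(slope = slope, intercept = yb - slope * xb, r = r,
                 p_value = p, n = n), class = "linregress")
}

#' @export
print.linregress <- function(x, ...) {
  cat(sprintf("linregress: slope %.4g, intercept %.4g, R = %.3f, p = %.3g, n = %d\n",
              x$slope, x$intercept, x$r, x$p_value, x$n))
  invisible(x)
}

#' Pair DFI measurements with their nearest MFI measurements
#'
#' For each DFI record the same-mouse MFI record with the smallest
#' absolute date difference is selected; the pair is kept only when the
#' two assays are fewer than `max_gap_days` whole days apart (strict
#' inequality). When two MFI records are equidistant the earlier one is
#' taken. The DFI assay date is the beginning of video acquisition (the
#' first full day).
#'
#' @param dfi_records Data frame with `mouse_id`, `date` (`Date`) and a
#'   `dfi` value column.
#' @param mfi_records Data frame with `mouse_id`, `date` (`Date`) and an
#'   `overall` (or `mfi`) value column.
#' @param max_gap_days Pairing window; pairs with `|gap| >= max_gap_days`
#'   are dropped. Default 8 (i.e. gaps of at most 7 days qualify).
#' @return Data frame with one row per paired DFI record: `mouse_id`,
#'   `dfi_date`, `mfi_date`, `gap_days`, `dfi`, `mfi`, plus `age_days`
#'   and `sex` columns when present in `dfi_records`.
#' @export
pair_mfi_dfi <- function(dfi_records, mfi_records, max_gap_days = 8) {
  mfi_val <- if ("mfi" %in% names(mfi_records)) "mfi" else "overall"
  out <- list()
  mdate <- as.Date(mfi_records$date)
  ddate <- as.Date(dfi_records$date)
  for (i in seq_len(nrow(dfi_records))) {
    j <- which(mfi_records$mouse_id == dfi_records$mouse_id[i])
    if (length(j) == 0) next
    gap <- abs(as.integer(mdate[j] - ddate[i]))
    best_gap <- min(gap)
    if (best_gap >= max_gap_days) next
    cand <- j[gap == best_gap]
    best <- cand[which.min(as.numeric(mdate[cand]))]
    row <- data.frame(mouse_id = dfi_records$mouse_id[i],
                      dfi_date = ddate[i], mfi_date = mdate[best],
                      gap_days = best_gap,
                      dfi = dfi_records$dfi[i],
                      mfi = mfi_records[[mfi_val]][best],
                      stringsAsFactors = FALSE)
    for (extra in c("age_days", "sex")) {
      if (extra %in% names(dfi_records)) row[[extra]] <- dfi_records[[extra]][i]
    }
    out[[length(out) + 1L]] <- row
  }
  if (length(out) == 0) {
    return(data.frame(mouse_id = character(0), dfi_date = as.Date(character(0)),
                      mfi_date = as.Date(character(0)), gap_days = integer(0),
                      dfi = numeric(0), mfi = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Age-normalized residual correlation between MFI and DFI
#'
#' Both MFI and DFI correlate with chronological age, so their mutual
#' correlation could be mediated by age rather than frailty. To test
#' this, MFI and DFI are each regressed against age on the paired subset,
#' residuals from the two fits are computed for every pair, and the MFI
#' residuals are regressed against the DFI residuals.
#'
#' @param pairs Data frame from [pair_mfi_dfi()] with an `age_days`
#'   column.
#' @return List with `mfi_vs_age`, `dfi_vs_age`, and `residual`
#'   ([linregress()] results), plus `residual_mfi` and `residual_dfi`
#'   vectors.
#' @export
age_residual_correlation <- function(pairs) {
  if (!"age_days" %in% names(pairs)) stop("pairs must carry age_days")
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  fit_m <- linregress(pairs$age_days, pairs$mfi)
  fit_d <- linregress(pairs$age_days, pairs$dfi)
  res_m <- pairs$mfi - (fit_m$intercept + fit_m$slope * pairs$age_days)
  res_d <- pairs$dfi - (fit_d$intercept + fit_d$slope * pairs$age_days)
  list(mfi_vs_age = fit_m, dfi_vs_age = fit_d,
       residual = linregress(res_m, res_d),
       residual_mfi = res_m, residual_dfi = res_d)
}

#' Pairwise Pearson correlation matrix of frailty components
#'
#' Correlations are computed over pairwise-complete observations. Sparse
#' MFI items — those observed non-zero 5 times or fewer across the study —
#' are excluded before computing the matrix. Constant columns yield
#' missing correlations.
#'
#' @param tab Data frame of numeric component columns (DFI components,
#'   MFI items, age, ...).
#' @param mfi_items Character vector naming which columns are MFI items
#'   and therefore subject to the non-zero filter.
#' @param min_nonzero Strict lower bound on non-zero observations for MFI
#'   items. Default 5.
#' @return Symmetric correlation matrix (unit diagonal for non-constant
#'   columns), with an attribute `excluded` naming dropped items.
#' @export
component_correlation_matrix <- function(tab, mfi_items = character(0),
                                         min_nonzero = 5) {
  keep <- names(tab)
  excluded <- character(0)
  for (nm in intersect(mfi_items, names(tab))) {
    nz <- sum(tab[[nm]] != 0, na.rm = TRUE)
    if (nz <= min_nonzero) {
      keep <- setdiff(keep, nm)
      excluded <- c(excluded, nm)
    }
  }
  m <- as.matrix(tab[, keep, drop = FALSE])
  cm <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  diag(cm)[!is.na(diag(cm))] <- 1
  attr(cm, "excluded") <- excluded
  cm
}

#' WPGMA hierarchical clustering of a correlation matrix
#'
#' Correlations are converted to distances (`1 - R`, or `1 - |R|`) and
#' clustered by WPGMA (weighted pair-group method with arithmetic mean):
#' at each step the closest pair of clusters merges, and the merged
#' cluster's distance to every other cluster is the unweighted mean of
#' its two children's distances. Ties are broken toward the lowest
#' column indices, making the merge order deterministic.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (e.g. from
#'   [component_correlation_matrix()]).
#' @param transform `"one_minus_r"` (default) or `"one_minus_abs_r"`.
#' @return An object of class `hclust` (merge matrix, heights, order,
#'   labels), usable with [stats::cophenetic()], plotting, and
#'   [write_dendrogram_newick()]. The merge heights are additionally
#'   returned in the `height` component in merge order.
#' @export
wpgma_cluster <- function(corr, transform = c("one_minus_r",
                                              "one_minus_abs_r")) {
  transform <- match.arg(transform)
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr) || max(abs(corr - t(corr)), na.rm = TRUE) > 1e-8) {
    stop("correlation matrix must be symmetric")
  }
  if (any(is.na(corr))) stop("correlation matrix contains missing values")
  if (max(abs(diag(corr) - 1)) > 1e-8) stop("diagonal must be 1")
  if (n < 2) stop("need at least 2 items to cluster")
  d <- if (transform == "one_minus_r") 1 - corr else 1 - abs(corr)
  labels <- colnames(corr)
  if (is.null(labels)) labels <- paste0("V", seq_len(n))

  active <- seq_len(n)          # current cluster ids (neg = leaf position)
  id <- -seq_len(n)             # hclust convention: leaves negative
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  D <- d
  diag(D) <- Inf
  for (step in seq_len(n - 1)) {
    k <- nrow(D)
    # lowest-index tie-break: scan column-major for the minimum
    min_val <- min(D)
    hit <- which(D == min_val, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- min_val
    if (step < n - 1L) {
      new_row <- (D[i, ] + D[j, ]) / 2
      keep <- setdiff(seq_len(k), c(i, j))
      D <- rbind(cbind(D[keep, keep, drop = FALSE], new_row[keep]),
                 c(new_row[keep], Inf))
      id <- c(id[keep], step)
    }
  }
  # leaf ordering by recursive traversal of the merge tree
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(merge[node, 1]), expand(merge[node, 2]))
  }
  hc <- list(merge = merge, height = height,
             order = expand(n - 1L), labels = labels,
             method = "wpgma", dist.method = transform,
             call = match.call())
  class(hc) <- "hclust"
  hc
}

#' Write a dendrogram as Newick
#'
#' @param hc An `hclust` object (e.g. from [wpgma_cluster()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(hc, path) {
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
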