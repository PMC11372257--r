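#' Spearman rank correlation with small-sample exact p-value
#'
#' `rho` is the Pearson correlation of midranks (ties allowed).  The
#' two-sided p-value uses the exact permutation null (full enumeration of
#' all `n!` rank permutations) for `n <= 9` and the t-approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` otherwise.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param label optional pair label carried into the result.
#' @return List of class `surrogacy_result`: `label`, `rho`, `p`, `n`,
#'   `method`.
#' @export
spearman <- function(x, y, label = "x vs y") {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) {
    keep <- !(is.na(x) | is.na(y))
    x <- x[keep]
    y <- y[keep]
    if (length(x) < 3) stop("fewer than 3 complete pairs")
  }
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0)
    stop("Spearman rho undefined for a constant vector")
  rho <- cor(rx, ry)
  if (n <= 9) {
    perms <- .permutations(n)
    # rho is affine in sum(rx * ry[perm]); enumerate that inner product
    s_perm <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    mu <- n * mean(rx) * mean(ry)
    sc <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    rho_perm <- (s_perm - mu) / sc
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * pt(-abs(tt), df = n - 2))
    method <- "t approximation"
  }
  structure(list(label = label, rho = rho, p = p, n = n, method = method),
            class = "surrogacy_result")
}

# all permutations of 1:n as a matrix (n! rows); n <= 9 keeps this small
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    blk <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                 if (pos <= n - 1) sub[, pos:(n - 1), drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(blk)
    r <- r + nrow(sub)
  }
  out
}

#' @export
print.surrogacy_result <- function(x, ...) {
  cat(sprintf("Spearman %s: rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$label, x$rho, x$p, x$n, x$method))
  invisible(x)
}

#' Exact paired Wilcoxon signed-rank test
#'
#' Zero differences are dropped; absolute differences are midranked (exact
#' tie handling) and the null distribution of the positive rank sum `W+` is
#' built by full enumeration over all `2^n` sign assignments.  The reported
#' statistic is the smaller of the two rank sums, and the two-sided p-value
#' is `P(W+ <= w) + P(W+ >= T - w)` with `T = n(n+1)/2`, which reproduces
#' the printed values of small paired designs exactly (e.g. `n = 7`, all
#' positive: `p = 2/128 = 0.015625`).
#'
#' @param differences paired differences.
#' @return List of class `paired_test_result`: `n`, `statistic` (smaller
#'   rank sum), `p`, `W_plus`.
#' @export
wilcoxon_exact <- function(differences) {
  d <- differences[!is.na(differences)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("all differences are zero")
  if (n > 20) stop("exact enumeration supported for n <= 20")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  total <- n * (n + 1) / 2
  # enumerate W+ over all 2^n sign assignments on doubled (integer) ranks
  r2 <- as.integer(round(2 * r))
  counts <- numeric(sum(r2) + 1L)  # index = value + 1
  counts[1] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  support <- (seq_along(counts) - 1L) / 2
  prob <- counts / 2^n
  w_small <- min(w_plus, total - w_plus)
  p <- sum(prob[support <= w_small + 1e-9]) +
    sum(prob[support >= total - w_small - 1e-9])
  p <- min(1, p)
  structure(list(n = n, statistic = w_small, W_plus = w_plus, p = p),
            class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf(
    "Exact Wilcoxon signed-rank: n = %d, W = %g, two-sided p = %.4g\n",
    x$n, x$statistic, x$p))
  invisible(x)
}

# the fixed surrogate/reference pair set of the analysis
.SURROGACY_PAIRS <- list(
  c("SUV", "VT"), c("SUVR", "VT"), c("SUVR", "VT_vb"),
  c("K_Logan", "VT"), c("K_Logan", "VT_vb"),
  c("Ki_2T6P", "SUVR"), c("Ki_2T5P", "SUVR"))

#' Surrogacy analysis of static measures against kinetic macroparameters
#'
#' Spearman correlations over the regions of a macroparameter table for the
#' fixed pair set: (SUV, VT), (SUVR, VT), (SUVR, VT_vb), (K_Logan, VT),
#' (K_Logan, VT_vb), (Ki_2T6P, SUVR), (Ki_2T5P, SUVR).  No
#' multiple-comparison correction is applied.
#'
#' @param macro_table data frame with columns `SUV`, `SUVR`, `K_Logan`,
#'   `VT`, `VT_vb`, `Ki_2T6P`, `Ki_2T5P` (one row per region, >= 3 rows).
#' @return List of [spearman()] results, one per pair.
#' @export
surrogacy_analysis <- function(macro_table) {
  need <- unique(unlist(.SURROGACY_PAIRS))
  missing_cols <- setdiff(need, names(macro_table))
  if (length(missing_cols))
    stop("macro table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(macro_table) < 3) stop("need at least 3 regions")
  lapply(.SURROGACY_PAIRS, function(pr)
    spearman(macro_table[[pr[1]]], macro_table[[pr[2]]],
             label = paste(pr[1], "vs", pr[2])))
}

#' Paired pre/post comparison of a quantity across matched regions
#'
#' Matches rows of two macro/parameter tables by region label and runs the
#' exact Wilcoxon signed-rank test on the paired differences
#' (post minus pre) of column `what`.
#'
#' @param pre,post data frames with a `region` column.
#' @param what column to compare.
#' @param regions optional region subset (default: all shared regions).
#' @return A [wilcoxon_exact()] result with the region set attached.
#' @export
paired_region_test <- function(pre, post, what, regions = NULL) {
  if (is.null(regions)) regions <- union(pre$region, post$region)
  unmatched <- c(setdiff(regions, pre$region), setdiff(regions, post$region))
  if (length(unmatched))
    stop("unmatched region label(s): ", paste(unique(unmatched),
                                              collapse = ", "))
  a <- pre[[what]][match(regions, pre$region)]
  b <- post[[what]][match(regions, post$region)]
  res <- wilcoxon_exact(b - a)
  res$what <- what
  res$regions <- regions
  res
}
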