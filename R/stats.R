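#' Pearson correlation with parametric p-value
#'
#' Product-moment correlation with the two-sided p-value from the
#' t-transform on n-2 degrees of freedom (via [stats::cor.test()]).
#' Pairs with a missing value in either vector are dropped, and the
#' effective n is reported: with nine-subject cohorts, every test must
#' carry its own n.
#'
#' @param x,y Numeric vectors of equal length.
#' @param labels Optional length-2 character vector naming the variable
#'   pair.
#' @return An object of class `rr_cor`: list with `variable_x`,
#'   `variable_y`, `n`, `r`, `p_parametric`, `p_permutation` (`NA` until
#'   [permutation_p()] is run), `n_permutations`.
#' @export
pearson_r <- function(x, y, labels = c(deparse1(substitute(x)),
                                       deparse1(substitute(y)))) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(variable_x = labels[1], variable_y = labels[2], n = n,
                 r = unname(ct$estimate), p_parametric = ct$p.value,
                 p_permutation = NA_real_, n_permutations = 0L),
            class = "rr_cor")
}

#' @export
print.rr_cor <- function(x, ...) {
  cat(sprintf("Pearson r(%s, %s) = %.3f, n = %d, p = %.4g",
              x$variable_x, x$variable_y, x$r, x$n, x$p_parametric))
  if (is.finite(x$p_permutation))
    cat(sprintf(" (permutation p = %.4g, B = %d)",
                x$p_permutation, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Permutation p-value for a Pearson correlation
#'
#' Small-sample safeguard for the parametric p: permutes `y` with a
#' seeded stream and reports
#' `p = (1 + #\{|r*| >= |r_obs|\}) / (n_permutations + 1)`, the
#' add-one two-sided Monte-Carlo estimate, which is never exactly zero.
#'
#' @inheritParams pearson_r
#' @param n_permutations Number of permutations (>= 99).
#' @param seed Integer seed for the permutation stream.
#' @return Numeric p-value in `[1/(B+1), 1]`.
#' @export
permutation_p <- function(x, y, n_permutations = 999, seed = 1L) {
  stopifnot(length(x) == length(y), n_permutations >= 99)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("insufficient data: fewer than 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  r_obs <- stats::cor(x, y)
  xc <- x - mean(x)
  denom_x <- sqrt(sum(xc^2))
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_permutations)) {
    yp <- y[sample.int(n)]
    yc <- yp - mean(yp)
    r_b <- sum(xc * yc) / (denom_x * sqrt(sum(yc^2)))
    if (abs(r_b) >= abs(r_obs) - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (n_permutations + 1)
}

#' Paired t contrast (peak vs at-emergence frequencies)
#'
#' Two-sided paired t-test via [stats::t.test()], reporting the means and
#' sds of both arms as they are printed in peak-vs-emergence contrasts:
#' `t = mean(pre - post) / (sd(pre - post)/sqrt(n))` on n-1 degrees of
#' freedom.
#'
#' @param pre,post Numeric vectors of equal length (n >= 2); pairs with a
#'   missing value in either arm are dropped.
#' @param label Contrast label.
#' @return Object of class `rr_paired`: list with `label`, `n`,
#'   `mean_pre`, `sd_pre`, `mean_post`, `sd_post`, `t`, `df`, `p`.
#' @export
paired_t <- function(pre, post, label = "paired contrast") {
  if (length(pre) != length(post)) stop("pre and post must have equal length")
  keep <- is.finite(pre) & is.finite(post)
  pre <- pre[keep]; post <- post[keep]
  n <- length(pre)
  if (n < 2) stop("insufficient data: fewer than 2 complete pairs")
  if (stats::sd(pre - post) == 0)
    stop("degenerate contrast: zero-variance differences")
  tt <- stats::t.test(pre, post, paired = TRUE, alternative = "two.sided")
  structure(list(label = label, n = n,
                 mean_pre = mean(pre), sd_pre = stats::sd(pre),
                 mean_post = mean(post), sd_post = stats::sd(post),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value),
            class = "rr_paired")
}

#' @export
print.rr_paired <- function(x, ...) {
  cat(sprintf("%s: %.3g (±%.2g) -> %.3g (±%.2g), t(%d) = %.3f, p = %.4g, n = %d\n",
              x$label, x$mean_pre, x$sd_pre, x$mean_post, x$sd_post,
              x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Cohen's kappa for two coders
#'
#' Chance-corrected nominal agreement
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with the expected agreement
#' \eqn{p_e} from the product of the coders' marginal label frequencies.
#' When both coders assign a single identical label to every item
#' (\eqn{p_e = 1}), agreement is perfect but chance-uncorrectable; by
#' convention 1 is returned with a warning.
#'
#' @param labels_a,labels_b Equal-length vectors of categorical labels
#'   over a shared category space.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(rep(c("a", "b"), 10), rep(c("a", "b"), 10))  # 1
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (length(labels_a) < 1) stop("empty label vectors")
  labels_a <- as.character(labels_a)
  labels_b <- as.character(labels_b)
  lev <- sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < 1e-12) {
    warning("both coders constant with the same label (p_e = 1); kappa defined as 1 by convention")
    return(1)
  }
  (p_o - p_e) / (1 - p_e)
}
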