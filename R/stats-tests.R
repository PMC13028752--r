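# Univariate statistical tests used for donor-group comparison. Standard
# tests wrap the stats routines; the Mann-Whitney U implements its own exact
# small-sample path because the reporting convention (U for the first group,
# two-sided enumeration p) is pinned down here.

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, 3 to 5000 non-constant observations.
#' @return A one-row tibble: `statistic` (W), `p_value`, `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) {
    stop("Shapiro-Wilk requires between 3 and 5000 observations", call. = FALSE)
  }
  if (min(values) == max(values)) {
    stop("Shapiro-Wilk is undefined for constant input", call. = FALSE)
  }
  ht <- stats::shapiro.test(values)
  tibble::tibble(statistic = unname(ht$statistic),
                 p_value = ht$p.value, n = n)
}

#' Mann-Whitney U test
#'
#' Rank-sum test for a difference between two independent groups. For small
#' untied samples (`min(n_a, n_b) <= 8`, no ties) the two-sided p value is
#' computed by exact enumeration of all rank assignments; otherwise the
#' normal approximation with tie correction is used (no continuity
#' correction, so identical groups give p = 1). `U` is reported for the
#' first group: the number of (a, b) pairs with a > b, counting ties as 1/2.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return A one-row tibble: `u`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_a`, `n_b`.
#' @export
mann_whitney <- function(group_a, group_b) {
  a <- group_a[!is.na(group_a)]; b <- group_b[!is.na(group_b)]
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both groups must be non-empty", call. = FALSE)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  has_ties <- anyDuplicated(pooled) > 0
  nn <- na * nb
  if (!has_ties && min(na, nb) <= 8) {
    ranks <- seq_len(na + nb)
    assignments <- utils::combn(na + nb, na)
    us <- colSums(matrix(ranks[assignments], nrow = na)) - na * (na + 1) / 2
    lo <- min(u, nn - u); hi <- max(u, nn - u)
    p <- (sum(us <= lo) + sum(us >= hi)) / length(us)
    p <- min(p, 1)
    method <- "exact"
  } else {
    n <- na + nb
    ties <- table(pooled)
    sigma2 <- nn / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - nn / 2) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approx"
  }
  tibble::tibble(u = u, p_value = p, method = method, n_a = na, n_b = nb)
}

#' Pearson correlation with two-sided t test
#'
#' @param x,y Paired numeric vectors, `n >= 3`, both non-constant.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (min(x) == max(x) || min(y) == max(y)) {
    stop("Pearson correlation is undefined for constant input", call. = FALSE)
  }
  ht <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' Holm correction across shear conditions
#'
#' Convenience wrapper around [stats::p.adjust()] for families of per-shear
#' group tests. Off by default in all reporting paths (per-condition p values
#' are reported uncorrected); provided for users who want family-wise
#' control.
#'
#' @param p_values Numeric vector of p values.
#' @return Holm-adjusted p values.
#' @export
holm_adjust <- function(p_values) stats::p.adjust(p_values, method = "holm")
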