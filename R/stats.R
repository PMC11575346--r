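# Statistical kernels shared by the proteomics and ScanLag modules.

#' Welch's two-sample t-test, vectorised over rows
#'
#' Computes the Welch (unequal-variance) t statistic, Welch-Satterthwaite
#' degrees of freedom and two-sided p-value for each row of two matrices.
#' Missing values are dropped per row; rows with fewer than two valid values
#' in either group get `NA` statistics.
#'
#' @param x,y Numeric matrices with one row per feature and one column per
#'   replicate. `NA` marks a missing observation.
#' @return A tibble with columns `n_x`, `n_y`, `mean_x`, `mean_y`, `t`, `df`
#'   and `p` (two-sided), one row per input row.
#' @examples
#' welch_t_rows(matrix(c(10, 12, 14), 1), matrix(c(20, 21, 22), 1))
#' @export
welch_t_rows <- function(x, y) {
  stopifnot(is.matrix(x), is.matrix(y), nrow(x) == nrow(y))
  n_x <- unname(rowSums(!is.na(x)))
  n_y <- unname(rowSums(!is.na(y)))
  mean_x <- unname(rowMeans(x, na.rm = TRUE))
  mean_y <- unname(rowMeans(y, na.rm = TRUE))
  var_x <- unname(apply(x, 1L, stats::var, na.rm = TRUE))
  var_y <- unname(apply(y, 1L, stats::var, na.rm = TRUE))
  ok <- n_x >= 2L & n_y >= 2L
  se2 <- var_x / n_x + var_y / n_y
  t <- ifelse(ok, (mean_x - mean_y) / sqrt(se2), NA_real_)
  df <- ifelse(
    ok,
    se2^2 / ((var_x / n_x)^2 / (n_x - 1L) + (var_y / n_y)^2 / (n_y - 1L)),
    NA_real_
  )
  p <- 2 * stats::pt(-abs(t), df)
  tibble(
    n_x = n_x, n_y = n_y,
    mean_x = ifelse(n_x > 0L, mean_x, NA_real_),
    mean_y = ifelse(n_y > 0L, mean_y, NA_real_),
    t = t, df = df, p = p
  )
}

#' Mann-Whitney U test (rank-sum test)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test. When both samples have at
#' most `exact_max` observations the p-value is computed by exhaustive
#' enumeration of all rank assignments (valid with ties); otherwise a
#' tie-corrected normal approximation (no continuity correction) is used.
#' Two identical samples with zero variance give p = 1 by convention.
#'
#' @param x,y Numeric vectors, both nonempty.
#' @param exact_max Largest per-group size at which exact enumeration is used.
#' @return A list with `u` (U statistic of `x`, counting `x > y` pairs with
#'   ties as 1/2), `p` (two-sided), `n_x`, `n_y` and `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6)) # exact p = 0.1
#' @export
mann_whitney_u <- function(x, y, exact_max = 8L) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    abort("both groups must be nonempty")
  }
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (stats::var(pooled) == 0) {
    return(list(u = u, p = 1, n_x = n1, n_y = n2, method = "degenerate"))
  }
  if (n1 <= exact_max && n2 <= exact_max) {
    # enumerate every way of assigning n1 of the pooled ranks to group x
    sel <- utils::combn(n1 + n2, n1)
    us <- colSums(matrix(r[sel], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-12)
    method <- "exact"
  } else {
    nn <- n1 + n2
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - tie_term)
    if (sigma2 <= 0) {
      return(list(u = u, p = 1, n_x = n1, n_y = n2, method = "degenerate"))
    }
    z <- (u - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  list(u = u, p = min(p, 1), n_x = n1, n_y = n2, method = method)
}
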