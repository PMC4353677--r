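#' Tie-corrected Spearman rank correlation
#'
#' Mid-rank Spearman rho: the Pearson correlation of the mid-ranks of `x` and
#' `y`. Returns `NA` if either vector is constant.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Spearman rho in \[-1, 1\], or `NA` for a constant input.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length.")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

# all permutations of 1..n as an (n! x n) matrix; n <= 9
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

# two-sided p for precomputed rho given ranks; exact permutation when n <= 9
# and x is tie-free, t-approximation otherwise
.spearman_p <- function(rho, rx, ry, exact_max_n = 9L) {
  n <- length(rx)
  if (is.na(rho)) return(1)
  tie_free <- !anyDuplicated(rx)
  if (n <= exact_max_n && tie_free) {
    perms <- .permutations(n)
    # rho over permutations of x against fixed y is linear in sum(rx_perm * ry)
    ry_c <- ry - mean(ry)
    rx_c <- rx - mean(rx)
    denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
    s <- matrix(rx_c[perms], nrow(perms), n) %*% ry_c
    rho_perm <- as.vector(s) / denom
    return(mean(abs(rho_perm) >= abs(rho) - 1e-12))
  }
  if (n < 3 || abs(rho) >= 1) return(if (abs(rho) >= 1 && n > 2) 0 else 1)
  tt <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' Spearman correlation test of an intra-pair difference against grade
#'
#' Tie-corrected Spearman rho with a two-sided p value: an exact permutation
#' p when there are at most 9 donors and the differences are tie-free,
#' otherwise the t approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}}.
#' A constant difference vector yields `rho = NA`, `p = 1`.
#'
#' @param delta Numeric vector, one intra-pair difference per donor.
#' @param grades Numeric grades (3--7), one per donor; must not all be equal.
#' @param exact_max_n Largest n for which the exact permutation p is used.
#' @return A list with elements `rho` and `p`.
#' @export
spearman_grade <- function(delta, grades, exact_max_n = 9L) {
  n <- length(delta)
  if (n < 4) abort("Spearman grade screen needs at least 4 donors.")
  if (length(grades) != n) abort("delta and grades must have equal length.")
  if (length(unique(grades)) == 1)
    abort("All grades equal: correlation with grade is undefined.")
  rx <- rank(delta)
  ry <- rank(grades)
  rho <- if (stats::sd(rx) == 0) NA_real_ else stats::cor(rx, ry)
  list(rho = rho, p = .spearman_p(rho, rx, ry, exact_max_n))
}

# Row-wise Spearman of a probes x donors matrix against one covariate.
# Returns tibble(rho, p). Uses the same exact-permutation rule as
# spearman_grade when applicable (shared permutation matrix across rows).
.spearman_matrix <- function(D, y, exact_max_n = 9L) {
  n <- ncol(D)
  if (stats::sd(y) == 0) {
    return(tibble(rho = rep(NA_real_, nrow(D)), p = rep(1, nrow(D))))
  }
  rx <- t(apply(D, 1, rank))
  if (nrow(D) == 1) rx <- matrix(rx, 1)
  ry <- rank(y)
  rx_c <- rx - rowMeans(rx)
  ry_c <- ry - mean(ry)
  den <- sqrt(rowSums(rx_c^2) * sum(ry_c^2))
  rho <- as.vector(rx_c %*% ry_c) / den
  rho[den == 0] <- NA_real_
  rho <- pmin(pmax(rho, -1), 1)

  p <- numeric(nrow(D))
  tie_free <- apply(rx, 1, function(r) !anyDuplicated(r))
  use_exact <- n <= exact_max_n & tie_free
  # t approximation
  idx_t <- which(!use_exact & !is.na(rho))
  if (length(idx_t)) {
    r <- rho[idx_t]
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
    pt_val <- 2 * stats::pt(-abs(tt), df = n - 2)
    pt_val[abs(r) >= 1] <- 0
    p[idx_t] <- if (n >= 3) pt_val else 1
  }
  if (any(use_exact)) {
    perms <- .permutations(n)
    P <- matrix(ry_c[perms], nrow(perms), n)
    s_perm <- rx_c[use_exact, , drop = FALSE] %*% t(P)   # rows x n!
    rho_perm <- s_perm / den[use_exact]
    obs <- abs(rho[use_exact])
    p[use_exact] <- rowMeans(abs(rho_perm) >= obs - 1e-12)
  }
  p[is.na(rho)] <- 1
  tibble(rho = rho, p = p)
}
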