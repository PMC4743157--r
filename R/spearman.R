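#' Spearman rank correlation test
#'
#' Correlation of ranks (midranks under ties) with a two-sided p-value.
#' For small samples (`n <= exact_n`, default 8) the p-value is exact: the
#' observed |rho| is compared against the full permutation distribution over
#' all `n!` orderings of one variable, which remains valid under ties. Above
#' that, the usual t approximation `t = rho * sqrt((n-2)/(1-rho^2))` on
#' `n - 2` degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param exact_n largest n for which the exact permutation p is computed.
#' @return A list with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approx"`).
#' @export
spearman_test <- function(x, y, exact_n = 8) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 3)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("constant input: Spearman correlation undefined")
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    perms <- all_permutations(n)
    a <- scale(rx)[, 1]; b <- scale(ry)[, 1]
    rho_perm <- as.vector(matrix(b[perms], nrow = nrow(perms)) %*% a) / (n - 1)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approx"
  }
  list(rho = rho, p = p, n = n, method = method)
}

# all permutations of 1:n as an n! x n matrix, lexicographic order
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    block <- cbind(first, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}
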