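# One-tailed Mann-Whitney U test, implemented from first principles.
#
# Three routes, chosen automatically and reported in the result:
#   exact        — tie-free data with n_a + n_b <= 25: the exact null
#                  distribution of U by the standard counting recurrence.
#   enumeration  — ties present but choose(n, n_a) small enough: the exact
#                  permutation distribution by full enumeration of group
#                  assignments.
#   normal       — otherwise: normal approximation with tie correction and a
#                  0.5 continuity correction.

#' One-tailed Mann-Whitney U test
#'
#' Tests whether values in one group tend to exceed those in the other.
#' U is reported for `group_a` (number of (a, b) pairs with a > b, ties
#' counting 1/2).
#'
#' @param group_a,group_b numeric vectors (nonempty)
#' @param alternative "a_greater" or "b_greater"
#' @param exact_limit use exact routes when n_a + n_b is at most this
#' @param enumeration_limit maximum choose(n, n_a) for tie enumeration
#' @return an object of class `mw_test`: list with statistic (U for group_a),
#'   p.value, method, n_a, n_b, alternative
#' @export
mann_whitney_one_tailed <- function(group_a, group_b,
                                    alternative = c("a_greater", "b_greater"),
                                    exact_limit = 25,
                                    enumeration_limit = 2e5) {
  alternative <- match.arg(alternative)
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  na <- length(group_a); nb <- length(group_b)
  U_a <- .u_statistic(group_a, group_b)
  U_obs <- if (alternative == "a_greater") U_a else na * nb - U_a
  has_ties <- anyDuplicated(c(group_a, group_b)) > 0
  if (!has_ties && na + nb <= exact_limit) {
    p <- .mw_exact_p(U_obs, na, nb)
    method <- "exact"
  } else if (has_ties && na + nb <= exact_limit &&
             choose(na + nb, na) <= enumeration_limit) {
    p <- .mw_enumeration_p(group_a, group_b, U_obs, alternative)
    method <- "enumeration"
  } else {
    p <- .mw_normal_p(U_obs, group_a, group_b)
    method <- "normal"
  }
  structure(list(statistic = U_a, p.value = p, method = method,
                 n_a = na, n_b = nb, alternative = alternative),
            class = "mw_test")
}

# U for group_a with 1/2 for ties, via midranks.
.u_statistic <- function(a, b) {
  r <- rank(c(a, b))
  sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
}

# Exact tie-free null distribution of U by the counting recurrence
# c(u; m, n) = c(u - n; m - 1, n) + c(u; m, n - 1), memoised.
.mw_exact_p <- function(u_obs, m, n) {
  memo <- new.env(parent = emptyenv())
  cw <- function(u, mm, nn) {
    if (u < 0 || u > mm * nn) return(0)
    if (mm == 0 || nn == 0) return(as.numeric(u == 0))
    key <- paste(u, mm, nn)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- cw(u - nn, mm - 1, nn) + cw(u, mm, nn - 1)
    memo[[key]] <- val
    val
  }
  counts <- vapply(floor(u_obs):(m * n), cw, 0, mm = m, nn = n)
  sum(counts) / choose(m + n, m)
}

# Exact permutation distribution with ties: enumerate all group assignments.
.mw_enumeration_p <- function(a, b, u_obs, alternative) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  idx <- utils::combn(n, na)
  offs <- na * (na + 1) / 2
  u_all <- colSums(matrix(r[idx], nrow = na)) - offs
  if (alternative == "b_greater") u_all <- na * (n - na) - u_all
  mean(u_all >= u_obs - 1e-9)
}

# Normal approximation with tie correction and continuity correction.
.mw_normal_p <- function(u_obs, a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  mu <- na * nb / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) return(1)
  z <- (u_obs - mu - 0.5) / sqrt(sigma2)
  stats::pnorm(z, lower.tail = FALSE)
}

#' @export
print.mw_test <- function(x, ...) {
  cat("One-tailed Mann-Whitney U test (", x$method, " method)\n",
      "U = ", x$statistic, " (n_a = ", x$n_a, ", n_b = ", x$n_b, "), ",
      "alternative: ", x$alternative, "\n",
      "p = ", format(x$p.value, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Tidy a Mann-Whitney test result
#' @param x an `mw_test`
#' @param ... unused
#' @return one-row tibble with statistic, p.value, method, n_a, n_b,
#'   alternative
#' @export
tidy.mw_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 method = x$method, n_a = x$n_a, n_b = x$n_b,
                 alternative = x$alternative)
}

#' @rdname tidy.mw_test
#' @export
glance.mw_test <- function(x, ...) tidy.mw_test(x)

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
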