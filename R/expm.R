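#' Action of a Moran-generator matrix exponential on a vector
#'
#' Computes `v exp(Q t)` (left action, propagating a distribution forward)
#' or `exp(Q t) v` (right action, pulling back an indicator of a target
#' state) by uniformization: with \eqn{\Lambda = \max_i |q_{ii}|} and
#' \eqn{P = I + Q/\Lambda} (a substochastic non-negative matrix),
#' \deqn{v e^{Qt} = \sum_{n \ge 0} \mathrm{Pois}(n; \Lambda t)\, v P^n,}
#' truncated once the remaining Poisson mass is below `tol`.  All terms are
#' non-negative, so the sum is numerically stable for the long horizons
#' that fixation calculations need; no dense exponential is ever formed.
#'
#' @param Q Generator matrix (sparse `dgCMatrix` or base matrix); rows sum
#'   to zero.
#' @param v Numeric vector, `length(v) == nrow(Q)`.
#' @param t Time (>= 0).
#' @param side `"left"` for `v exp(Qt)`, `"right"` for `exp(Qt) v`.
#' @param tol Truncation tolerance on the neglected Poisson tail mass.
#' @return Numeric vector of the same length as `v`.
#' @export
expm_action <- function(Q, v, t, side = c("left", "right"), tol = 1e-14) {
  side <- match.arg(side)
  if (length(t) != 1L || is.na(t) || t < 0) {
    stop("`t` must be a single non-negative number", call. = FALSE)
  }
  v <- as.numeric(v)
  n <- nrow(Q)
  stopifnot(length(v) == n)
  if (t == 0) return(v)
  lambda <- max(-Matrix::diag(Q))
  if (lambda <= 0) return(v)

  m <- lambda * t
  nmax <- max(20, ceiling(stats::qpois(tol, m, lower.tail = FALSE) * 1.1) + 20)
  P <- Q / lambda
  Matrix::diag(P) <- Matrix::diag(P) + 1

  w <- v
  out <- stats::dpois(0, m) * w
  acc <- stats::dpois(0, m)
  for (nn in seq_len(nmax)) {
    w <- if (side == "left") as.numeric(w %*% P) else as.numeric(P %*% w)
    p <- stats::dpois(nn, m)
    if (p > 0) {
      out <- out + p * w
      acc <- acc + p
    }
    if (acc >= 1 - tol && nn > m) break
  }
  out
}
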