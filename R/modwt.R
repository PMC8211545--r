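# Translation-invariant (maximal-overlap) discrete wavelet transform with
# the LA(8) least-asymmetric filter and reflection boundary handling.
# Implemented in-package: no wavelet package is available in the target R
# stack. Only what the detrending step needs is provided: the forward
# pyramid and per-level detail (MRA) reconstruction.

# LA(8) scaling filter; sums to sqrt(2).
la8_scaling <- c(-0.075765714789341, -0.029635527645954,
                  0.497618667632459,  0.803738751805216,
                  0.297857795605542, -0.099219543576935,
                 -0.012603967262261,  0.032223100604078)

modwt_filters <- function() {
  g <- la8_scaling
  L <- length(g)
  h <- (-1)^(0:(L - 1)) * rev(g)        # quadrature mirror
  list(g = g / sqrt(2), h = h / sqrt(2))
}

circ_shift <- function(x, s) {
  # x[(t + s - 1) mod N + 1]: shift left by s (s may be negative)
  n <- length(x)
  x[((seq_len(n) - 1 + s) %% n) + 1L]
}

# forward pyramid on a circular series; returns details' coefficients
# W[[1..J]] and the level-J smooth coefficients V
modwt_forward <- function(x, J) {
  f <- modwt_filters()
  L <- length(f$g)
  v <- x
  W <- vector("list", J)
  for (j in seq_len(J)) {
    sj <- 2^(j - 1)
    w_new <- numeric(length(x))
    v_new <- numeric(length(x))
    for (l in 0:(L - 1)) {
      shifted <- circ_shift(v, -sj * l)
      w_new <- w_new + f$h[l + 1L] * shifted
      v_new <- v_new + f$g[l + 1L] * shifted
    }
    W[[j]] <- w_new
    v <- v_new
  }
  list(W = W, V = v)
}

# one inverse pyramid step: coefficients at level j -> level j-1
modwt_inv_step <- function(w, v, j) {
  f <- modwt_filters()
  L <- length(f$g)
  sj <- 2^(j - 1)
  out <- numeric(length(w))
  for (l in 0:(L - 1))
    out <- out + f$h[l + 1L] * circ_shift(w, sj * l) +
                 f$g[l + 1L] * circ_shift(v, sj * l)
  out
}

# MRA detail series for level j (zero smooth, zero other details)
modwt_detail <- function(W, j) {
  v <- numeric(length(W[[j]]))
  w <- W[[j]]
  for (jj in j:1) {
    v <- modwt_inv_step(w, v, jj)
    w <- numeric(length(v))
  }
  v
}

# MRA smooth series at level J
modwt_smooth <- function(V, J) {
  v <- V
  w <- numeric(length(V))
  for (jj in J:1) {
    v <- modwt_inv_step(w, v, jj)
    w <- numeric(length(v))
  }
  v
}

#' Multiresolution decomposition of a uniformly sampled series
#'
#' Maximal-overlap DWT multiresolution analysis with the LA(8) filter.
#' The series is reflected (`c(x, rev(x))`) before the circular
#' transform and the first half of each component retained, which avoids
#' wrap-around artifacts at the record edges. Detail level `j` carries
#' fluctuations with periods roughly `[2^j dt, 2^(j+1) dt]`.
#'
#' @param x Numeric series without `NA`.
#' @param n_levels Decomposition depth `J`.
#' @return List with `details` (matrix, `length(x)` rows x `J` columns)
#'   and `smooth` (the level-`J` trend). Details and smooth sum to `x`.
#' @export
modwt_mra <- function(x, n_levels = 5L) {
  stopifnot(is.numeric(x), !anyNA(x), length(x) >= 2L)
  xe <- c(x, rev(x))
  fw <- modwt_forward(xe, n_levels)
  n <- length(x)
  details <- vapply(seq_len(n_levels),
                    function(j) modwt_detail(fw$W, j)[seq_len(n)],
                    numeric(n))
  smooth <- modwt_smooth(fw$V, n_levels)[seq_len(n)]
  list(details = details, smooth = smooth)
}
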