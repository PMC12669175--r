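# State-space sequence engine.
#
# The continuous system  h'(t) = A h(t) + B x(t),  y(t) = C h(t)  is
# discretized with the bilinear transform,
#   Abar = (I - D/2 A)^-1 (I + D/2 A),  Bbar = (I - D/2 A)^-1 D B,  Cbar = C,
# which yields the recurrence h[n] = Abar h[n-1] + Bbar x[n], y[n] = Cbar h[n]
# (zero initial state), equivalently the causal convolution with kernel
# K[j] = Cbar Abar^j Bbar.  The selective variant makes B, C and the step
# size input-dependent per token and is computed in compiled code.

#' Continuous state-space system parameters
#'
#' @param A state-transition matrix (N x N) or a length-N vector holding a
#'   diagonal system.
#' @param B input map, length N.
#' @param C output map, length N.
#' @param delta positive discretization step size.
#' @return An object of class `ssm_params`.
#' @export
ssm_params <- function(A, B, C, delta) {
  diagonal <- is.null(dim(A))
  if (diagonal) A <- as.numeric(A) else A <- as.matrix(A)
  n <- if (diagonal) length(A) else nrow(A)
  if (n < 1L) stop("state dimension must be >= 1", call. = FALSE)
  if (!diagonal && ncol(A) != n) stop("A must be square", call. = FALSE)
  B <- as.numeric(B); C <- as.numeric(C)
  if (length(B) != n || length(C) != n)
    stop("B and C must have length equal to the state dimension", call. = FALSE)
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("delta must be a single positive real", call. = FALSE)
  structure(list(A = A, B = B, C = C, delta = delta,
                 n_state = n, diagonal = diagonal),
            class = "ssm_params")
}

#' Bilinear discretization of a state-space system
#'
#' @param p an [ssm_params].
#' @return An object of class `discrete_ssm` with fields `A_bar`, `B_bar`,
#'   `C_bar` (and `diagonal`). Fails if `(I - delta/2 A)` is singular.
#' @export
discretize <- function(p) {
  if (!inherits(p, "ssm_params")) stop("expected ssm_params", call. = FALSE)
  if (p$diagonal) {
    denom <- 1 - p$delta / 2 * p$A
    if (any(abs(denom) < 1e-14))
      stop("discretization failed: (I - delta/2 A) is singular", call. = FALSE)
    A_bar <- (1 + p$delta / 2 * p$A) / denom
    B_bar <- p$delta * p$B / denom
  } else {
    M <- diag(p$n_state) - p$delta / 2 * p$A
    A_bar <- tryCatch(solve(M, diag(p$n_state) + p$delta / 2 * p$A),
                      error = function(e)
                        stop("discretization failed: (I - delta/2 A) is singular",
                             call. = FALSE))
    B_bar <- solve(M, p$delta * p$B)
  }
  structure(list(A_bar = A_bar, B_bar = B_bar, C_bar = p$C,
                 n_state = p$n_state, diagonal = p$diagonal),
            class = "discrete_ssm")
}

#' Run the discrete state-space recurrence
#'
#' `h[n] = A_bar h[n-1] + B_bar x[n]`, `y[n] = C_bar h[n]`, with `h`
#' initialized to zero before the first sample.
#'
#' @param d a `discrete_ssm` from [discretize()].
#' @param x numeric input sequence, length >= 1.
#' @return Numeric output sequence of the same length.
#' @export
ssm_recurrence <- function(d, x) {
  if (!inherits(d, "discrete_ssm")) stop("expected discrete_ssm", call. = FALSE)
  x <- as.numeric(x)
  L <- length(x)
  if (L < 1L) stop("input sequence must have length >= 1", call. = FALSE)
  h <- numeric(d$n_state)
  y <- numeric(L)
  for (n in seq_len(L)) {
    h <- if (d$diagonal) d$A_bar * h + d$B_bar * x[n]
         else drop(d$A_bar %*% h) + d$B_bar * x[n]
    y[n] <- sum(d$C_bar * h)
  }
  y
}

#' Convolution kernel of a discrete state-space system
#'
#' `K[j] = C A_bar^j B_bar` for `j = 0 .. L-1`.
#'
#' @param d a `discrete_ssm`.
#' @param L kernel length.
#' @return Numeric vector of length `L`.
#' @export
ssm_kernel <- function(d, L) {
  v <- d$B_bar
  K <- numeric(L)
  for (j in seq_len(L)) {
    K[j] <- sum(d$C_bar * v)
    v <- if (d$diagonal) d$A_bar * v else drop(d$A_bar %*% v)
  }
  K
}

#' Run a discrete state-space system in convolutional (LTI) form
#'
#' Computes the causal convolution `y = K * x` with the kernel from
#' [ssm_kernel()]; identical (to rounding) to [ssm_recurrence()].
#'
#' @inheritParams ssm_recurrence
#' @return Numeric output sequence of the same length as `x`.
#' @export
ssm_convolution <- function(d, x) {
  if (!inherits(d, "discrete_ssm")) stop("expected discrete_ssm", call. = FALSE)
  x <- as.numeric(x)
  L <- length(x)
  if (L < 1L) stop("input sequence must have length >= 1", call. = FALSE)
  K <- ssm_kernel(d, L)
  y <- numeric(L)
  for (n in seq_len(L)) y[n] <- sum(K[seq_len(n)] * x[n:1])
  y
}

#' Parameters of a selective (input-dependent) state-space scan
#'
#' `B` and `C` are linear projections of each d-dimensional token
#' (`N x d` weight matrices); the step size is
#' `delta = softplus(wd . x + bd)`, strictly positive by construction; the
#' diagonal transition `a` is shared across tokens and initialized with
#' negative real parts (`-(1..N)`), keeping the bilinear step well posed.
#'
#' @param d token (channel) dimension.
#' @param n_state state dimension N per channel.
#' @param Wb,Wc optional `N x d` projection matrices (default: Gaussian,
#'   sd `1/sqrt(d)`, drawn from the current RNG).
#' @param wd,bd optional step-size projection (length-d vector and scalar
#'   bias; defaults `0` and `softplus^-1(0.1)`).
#' @param a optional length-N diagonal of the shared transition matrix.
#' @return An object of class `selective_params`.
#' @export
selective_params <- function(d, n_state = 16L, Wb = NULL, Wc = NULL,
                             wd = NULL, bd = NULL, a = NULL) {
  d <- as.integer(d); n_state <- as.integer(n_state)
  if (d < 1L || n_state < 1L) stop("d and n_state must be >= 1", call. = FALSE)
  if (is.null(Wb)) Wb <- matrix(stats::rnorm(n_state * d, sd = 1 / sqrt(d)), n_state, d)
  if (is.null(Wc)) Wc <- matrix(stats::rnorm(n_state * d, sd = 1 / sqrt(d)), n_state, d)
  if (is.null(wd)) wd <- numeric(d)
  if (is.null(bd)) bd <- log(expm1(0.1))     # softplus(bd) = 0.1
  if (is.null(a)) a <- -seq_len(n_state)
  stopifnot(all(dim(Wb) == c(n_state, d)), all(dim(Wc) == c(n_state, d)),
            length(wd) == d, length(bd) == 1L, length(a) == n_state)
  structure(list(Wb = Wb, Wc = Wc, wd = as.numeric(wd), bd = as.numeric(bd),
                 a = as.numeric(a), d = d, n_state = n_state),
            class = "selective_params")
}

#' Selective state-space scan over a token sequence
#'
#' Every token is discretized with its own `(B, C, delta)` (projections of
#' the token) and the shared diagonal transition, then the recurrence
#' `h[n] = Abar_n h[n-1] + Bbar_n x[n]`, `y[n] = C_n h[n]` is run per
#' channel. Output has the same dimension and length as the input.
#'
#' @param sp a [selective_params].
#' @param X `d x L` matrix of tokens in columns (a plain vector is treated
#'   as a single-channel sequence).
#' @return A `d x L` matrix of output tokens.
#' @export
selective_scan <- function(sp, X) {
  if (!inherits(sp, "selective_params"))
    stop("expected selective_params", call. = FALSE)
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L)
  if (nrow(X) != sp$d)
    stop("token dimension mismatch: X has ", nrow(X), " rows, params expect ",
         sp$d, call. = FALSE)
  if (ncol(X) < 1L) stop("sequence must have length >= 1", call. = FALSE)
  selscan_forward_cpp(X, sp$Wb, sp$Wc, sp$wd, sp$bd, sp$a, FALSE)$Y
}
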