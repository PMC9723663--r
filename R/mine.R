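#' Maximal information coefficient (MICe)
#'
#' Equicharacteristic-matrix estimator of the maximal information
#' coefficient. For every grid dimension pair `(k, l)` with `k * l <= B(n)`
#' and `B(n) = max(4, floor(n^alpha))`, one axis is mass-equipartitioned into
#' `l` bins while the other is optimised into at most `k` bins by dynamic
#' programming over clump boundaries; the matrix entry is the larger of the
#' two axis orientations of mutual information normalised by
#' `log(min(k, l))`. MICe is the maximal entry. The estimator is rank-based:
#' it is invariant under strictly monotone transformations of either
#' variable, and symmetric in its arguments.
#'
#' @param x,y Numeric vectors of equal length `n >= 10` without missing
#'   values (drop pairwise-incomplete samples before calling).
#' @param alpha Grid-bound exponent (default 0.6).
#' @param max_clumps_factor The optimised axis is pre-binned into at most
#'   `max_clumps_factor * k` clumps before the dynamic programme; `Inf`
#'   disables the cap, making the optimisation exact over all clump
#'   boundaries.
#' @return A single value in `[0, 1]`. Constant input yields 0 with a
#'   warning.
#' @seealso [tic_e()], [mine_statistics()], [null_calibration()]
#' @export
mic_e <- function(x, y, alpha = 0.6, max_clumps_factor = 5) {
  mine_statistics(x, y, alpha, max_clumps_factor)$mic
}

#' Total information coefficient (TICe)
#'
#' Sum of the normalised equicharacteristic-matrix entries over all
#' admissible grid dimension pairs (see [mic_e()] for the grid definition).
#' TICe is zero only when every entry is zero, and always dominates MICe.
#'
#' @inheritParams mic_e
#' @return A non-negative value.
#' @export
tic_e <- function(x, y, alpha = 0.6, max_clumps_factor = 5) {
  mine_statistics(x, y, alpha, max_clumps_factor)$tic
}

#' MICe and TICe in one pass
#'
#' @inheritParams mic_e
#' @return List with elements `mic`, `tic`, `B` (the grid bound) and
#'   `n`.
#' @export
mine_statistics <- function(x, y, alpha = 0.6, max_clumps_factor = 5) {
  xy <- check_mine_input(x, y)
  if (xy$degenerate) {
    warning("constant input vector: MICe/TICe are 0 by definition")
    return(list(mic = 0, tic = 0,
                B = max(4L, floor(length(x)^alpha)), n = length(x),
                degenerate = TRUE))
  }
  res <- mine_stat_cpp(as.numeric(x), as.numeric(y), alpha, max_clumps_factor)
  list(mic = res$mic, tic = res$tic, B = res$B, n = length(x),
       degenerate = FALSE)
}

#' Equicharacteristic entry matrix
#'
#' Exposes the full normalised entry matrix underlying MICe/TICe; intended
#' for diagnostics and for validating the dynamic programme against direct
#' enumeration.
#'
#' @inheritParams mic_e
#' @return Matrix with rows `k = 2, 3, ...` and columns `l = 2, 3, ...`;
#'   inadmissible entries (`k * l > B`) are `NA`.
#' @export
mine_matrix <- function(x, y, alpha = 0.6, max_clumps_factor = 5) {
  xy <- check_mine_input(x, y)
  if (xy$degenerate) stop("constant input vector has no entry matrix")
  m <- mine_matrix_cpp(as.numeric(x), as.numeric(y), alpha, max_clumps_factor)
  dimnames(m) <- list(k = seq_len(nrow(m)) + 1L, l = seq_len(ncol(m)) + 1L)
  m
}

check_mine_input <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 10) stop("MICe/TICe require n >= 10")
  if (anyNA(x) || anyNA(y))
    stop("missing values: drop pairwise-incomplete samples before calling")
  list(degenerate = (length(unique(x)) < 2 || length(unique(y)) < 2))
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (average ranks for ties).
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @return Correlation in `[-1, 1]`, or `NA` with a warning for constant
#'   input (such edges are dropped downstream).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("spearman_rho requires n >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warning("constant input vector: Spearman rho undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Null calibration of the MICe threshold
#'
#' Monte-Carlo estimate of the probability that MICe of two independent
#' standard-normal vectors of length `n` meets a threshold. Used to check
#' that a network-inclusion threshold corresponds to the intended tail
#' probability under independence.
#'
#' @param n Sample size per replicate.
#' @param n_reps Number of null replicates (>= 1000 recommended).
#' @param threshold MICe threshold whose tail probability is estimated.
#' @param seed Integer seed.
#' @param alpha,max_clumps_factor Estimator parameters, see [mic_e()].
#' @return List with `prob` (the empirical tail probability), `n`,
#'   `n_reps`, `threshold`, and `mic` (the replicate values).
#' @export
null_calibration <- function(n, n_reps = 1000, threshold = 0.178, seed = 1,
                             alpha = 0.6, max_clumps_factor = 5) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  set.seed(seed)
  mic <- vapply(seq_len(n_reps), function(i) {
    mine_stat_cpp(rnorm(n), rnorm(n), alpha, max_clumps_factor)$mic
  }, numeric(1))
  list(prob = mean(mic >= threshold), n = n, n_reps = n_reps,
       threshold = threshold, mic = mic)
}
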