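# Amino-acid substitution model: JTT exchangeabilities, discrete-gamma rate
# variation and an invariant-site class. All phylogenetic machinery in the
# package (pairwise ML distances, pruning likelihood, SH test) consumes the
# object built here.

#' @useDynLib hgtscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# One-letter alphabet in the classical substitution-matrix order
# (PAML/molphy convention). All integer coding in the package uses this order.
AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Jones-Taylor-Thornton (1992) exchangeability counts, lower triangle,
# column-wise in AA_ORDER, and the accompanying stationary frequencies.
.jtt_lower <- c(
  58, 54, 81, 56, 57, 105, 179, 27, 36, 30, 35, 54, 15, 194, 378, 475, 9, 11,
  298, 45, 16, 113, 310, 29, 137, 328, 22, 38, 646, 44, 5, 74, 101, 64, 126,
  20, 17, 528, 34, 86, 58, 81, 391, 47, 12, 263, 30, 10, 15, 503, 232, 8, 70,
  16, 10, 49, 767, 130, 112, 11, 7, 26, 15, 4, 15, 59, 38, 4, 46, 31, 9, 5,
  59, 69, 17, 23, 7, 31, 78, 14, 223, 42, 115, 209, 62, 323, 26, 597, 9, 72,
  292, 43, 4, 164, 53, 51, 18, 24, 20, 119, 26, 12, 9, 181, 18, 5, 18, 30,
  32, 10, 7, 45, 23, 6, 6, 27, 14, 5, 24, 201, 33, 55, 8, 47, 16, 56, 45, 33,
  40, 115, 73, 46, 8, 573, 11, 229, 21, 479, 89, 10, 40, 245, 9, 32, 961, 14,
  388, 248, 102, 59, 25, 52, 24, 180, 65, 4, 21, 47, 103, 10, 8, 14, 43, 16,
  29, 226, 24, 18, 323, 17, 92, 12, 53, 536, 62, 285, 118, 6, 10, 23, 477,
  35, 63, 38, 12, 21, 112, 71, 25, 16)

.jtt_freq <- c(
  0.07674792, 0.05169095, 0.04264496, 0.05154395, 0.01980298, 0.04075196,
  0.06182994, 0.07315193, 0.02294398, 0.05376095, 0.09190391, 0.05867594,
  0.02382598, 0.04012596, 0.05090095, 0.06876493, 0.05856494, 0.01426099,
  0.03210197, 0.06600493)

jtt_exchangeability <- function() {
  R <- matrix(0, 20, 20, dimnames = list(AA_ORDER, AA_ORDER))
  R[lower.tri(R)] <- .jtt_lower
  R + t(R)
}

#' Discrete-gamma category rates
#'
#' Rates of the `n_cat` equiprobable categories of a Gamma(alpha, alpha)
#' distribution, represented by category medians and rescaled so the
#' category mean is exactly 1.
#'
#' @param alpha Gamma shape parameter (> 0). Small alpha = strong rate
#'   heterogeneity across sites.
#' @param n_cat Number of categories.
#' @return Numeric vector of length `n_cat`, mean 1.
#' @export
gamma_rates <- function(alpha, n_cat = 4L) {
  stopifnot(alpha > 0, n_cat >= 1)
  if (n_cat == 1L) return(1)
  p <- (seq_len(n_cat) - 0.5) / n_cat
  r <- stats::qgamma(p, shape = alpha, rate = alpha)
  r / mean(r)
}

#' Build an amino-acid substitution model
#'
#' Constructs a reversible JTT rate matrix with discrete-gamma rate
#' variation and an invariant-site class, normalized so the expected
#' substitution rate over variable and invariant sites is 1: branch
#' lengths are expected substitutions per site.
#'
#' @param alpha Gamma shape; `NULL` disables rate variation (single rate).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param n_cat Number of discrete gamma categories.
#' @return An object of class `hgt_subst_model` holding the rate matrix, its
#'   spectral decomposition, stationary frequencies, category rates and the
#'   invariant proportion.
#' @examples
#' m <- subst_model(alpha = 1, p_inv = 0.1)
#' P <- prob_matrix(m, 0.5)
#' rowSums(P)  # each ~1
#' @export
subst_model <- function(alpha = NULL, p_inv = 0, n_cat = 4L) {
  stopifnot(p_inv >= 0, p_inv < 1)
  pi <- .jtt_freq / sum(.jtt_freq)
  ex <- jtt_exchangeability()
  Q <- ex * rep(pi, each = 20)      # q_ij = s_ij * pi_j
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))          # expected rate under the raw matrix
  Q <- Q / mu                       # variable-site rate 1
  # invariant sites never change; rescale variable sites so the overall
  # expected rate stays 1
  if (p_inv > 0) Q <- Q / (1 - p_inv)
  # spectral decomposition via the symmetrized generator
  sp <- sqrt(pi)
  B <- Q * (sp / rep(sp, each = 20))  # B_ij = sqrt(pi_i) Q_ij / sqrt(pi_j)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  V <- eig$vectors / sp               # row-scaled: V_ij = U_ij / sqrt(pi_i)
  Vinv <- t(eig$vectors * sp)         # Vinv_ij = U_ji * sqrt(pi_j)
  rates <- if (is.null(alpha)) 1 else gamma_rates(alpha, n_cat)
  structure(
    list(Q = Q, freq = stats::setNames(pi, AA_ORDER), V = V,
         eigenvalues = eig$values, Vinv = Vinv, alpha = alpha,
         p_inv = p_inv, n_cat = if (is.null(alpha)) 1L else as.integer(n_cat),
         rates = rates, alphabet = AA_ORDER),
    class = "hgt_subst_model")
}

#' @export
print.hgt_subst_model <- function(x, ...) {
  cat("JTT substitution model\n")
  cat("  gamma shape:", if (is.null(x$alpha)) "none (single rate)"
      else format(x$alpha, digits = 4),
      " categories:", x$n_cat, "\n")
  cat("  invariant proportion:", format(x$p_inv, digits = 4), "\n")
  invisible(x)
}

#' Transition probability matrix
#'
#' `P(t) = exp(Q r t)` for one rate class, from the model's spectral
#' decomposition.
#'
#' @param model An `hgt_subst_model`.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param rate Rate multiplier (e.g. one of `model$rates`).
#' @return 20 x 20 row-stochastic matrix.
#' @export
prob_matrix <- function(model, t, rate = 1) {
  stopifnot(t >= 0, rate >= 0)
  P <- model$V %*% (exp(model$eigenvalues * rate * t) * model$Vinv)
  P[P < 0] <- 0
  dimnames(P) <- list(model$alphabet, model$alphabet)
  P
}

# Mixture transition matrix averaged over gamma categories (used by oracle
# paths and the expected-identity calculation; C++ code re-derives its own).
prob_matrix_mix <- function(model, t) {
  P <- matrix(0, 20, 20)
  for (r in model$rates) P <- P + prob_matrix(model, t, r)
  P / length(model$rates)
}

#' Expected sequence identity after divergence t
#'
#' Probability that a site is identical between an ancestor-descendant pair
#' (or, by reversibility, between two sequences) separated by `t` expected
#' substitutions per site, including the invariant-site class.
#'
#' @inheritParams prob_matrix
#' @return Scalar probability in (0, 1].
#' @export
expected_identity <- function(model, t) {
  P <- prob_matrix_mix(model, t)
  model$p_inv + (1 - model$p_inv) * sum(model$freq * diag(P))
}

# integer coding helpers -----------------------------------------------------

aa_to_int <- function(x) {
  # x: character string or vector of strings -> list of 0-based codes
  lapply(strsplit(toupper(x), ""), function(ch) {
    i <- match(ch, AA_ORDER)
    ifelse(is.na(i), -1L, i - 1L)
  })
}

int_to_aa <- function(codes) {
  lut <- c("-", AA_ORDER)        # index 1 = gap/unknown (-1 + 2)
  vapply(codes, function(v) {
    paste(lut[pmax(v, -1L) + 2L], collapse = "")
  }, character(1))
}
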