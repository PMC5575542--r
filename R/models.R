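# Amino-acid substitution models: WAG and Poisson (equal rates), with
# discrete-gamma rate heterogeneity.

#' One-letter amino-acid codes in the conventional (PAML) order
#'
#' Order used for all rate matrices, stationary frequency vectors and
#' posterior matrices in this package: A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @export
AA_CODES <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3_CODES <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
               Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
               L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
               S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

GAP_CHAR <- "-"

# Whelan & Goldman (2001) exchangeabilities, lower triangle, row-wise in
# AA_CODES order (R~A, N~A, N~R, D~A, ...), and stationary frequencies.
.WAG_EXCH <- c(
  0.5515710, 0.5098480, 0.7389980, 1.0270400, 0.9085980, 1.5828500,
  1.4167200, 0.3169540, 0.1933350, 0.3979150, 0.9062650, 0.8934960,
  0.2104940, 1.4385500, 3.3707900, 2.1211100, 0.1131330, 0.2407350,
  2.0060100, 0.6353460, 0.1473040, 0.5281910, 3.0355000, 0.4391570,
  0.5846650, 2.1371500, 0.1869790, 0.4976710, 5.3514200, 0.6831620,
  0.1027110, 0.6794890, 1.2241900, 0.5544130, 1.1639200, 0.3815330,
  0.2518490, 5.4294200, 0.2652560, 1.5436400, 0.9471980, 1.1255600,
  3.9562900, 0.5542360, 0.1315280, 3.0120100, 0.1982210, 0.0961621,
  0.1950810, 3.9742300, 2.0300600, 0.0719167, 1.0860000, 0.1962460,
  0.0302949, 0.6167830, 6.1741600, 0.8655840, 0.9306760, 0.0394370,
  0.0848047, 0.4798550, 0.1037540, 0.0467304, 0.4239840, 1.0717600,
  0.3748660, 0.1297670, 0.3257110, 0.1523350, 0.0988179, 0.0213520,
  0.3066740, 0.2489720, 0.1701350, 0.3842870, 0.0740339, 0.3904820,
  0.3980200, 0.1094040, 1.4076600, 0.5129840, 0.7170700, 0.5438330,
  1.0021400, 5.4694700, 0.3300520, 4.2941100, 0.1139170, 0.8694890,
  3.8949000, 1.5452600, 0.0999208, 0.9333720, 1.0288700, 0.8579280,
  0.2157370, 0.2277100, 0.3012810, 0.5677170, 0.5700250, 0.1273950,
  0.1542630, 2.5844300, 0.3151240, 0.0811339, 0.6823550, 0.7049390,
  0.8227650, 0.1565570, 0.1963030, 0.5887310, 0.2494100, 0.0304501,
  0.0613037, 0.3735580, 0.1741000, 0.0499310, 0.2435700, 1.3418200,
  0.2258330, 0.3369830, 0.1036040, 0.1872470, 0.1381900, 0.4994620,
  0.8904320, 0.4041410, 0.6793710, 0.6961980, 0.7401690, 0.4733070,
  0.2625690, 3.8734400, 0.1183580, 3.1709700, 0.3238320, 4.2574600,
  1.0594700, 0.0999288, 0.3194400, 1.4581600, 0.2124830, 0.4201700,
  7.8213000, 0.2575550, 4.8540200, 2.1151700, 0.4158440, 0.3447390,
  0.3266220, 0.6653090, 0.3986180, 1.8003400, 0.9342760, 0.0888360,
  0.5568960, 0.9671300, 1.3869800, 0.1375050, 0.1332640, 0.3054340,
  1.1906300, 0.1713290, 0.4939050, 1.5161200, 0.5157060, 0.4284370,
  2.0584500, 0.1614440, 0.5459310, 0.1719030, 1.5296400, 6.4542800,
  0.6498920, 1.6132800, 0.7953840, 0.1394050, 0.2160460, 0.3148870,
  4.3780200, 0.5237420, 0.7869930, 0.2327390, 0.1108640, 0.2911480,
  1.3882300, 2.4853900, 0.3653690, 0.3147300)

.WAG_FREQ <- c(0.0866279, 0.0439720, 0.0390894, 0.0570451, 0.0193078,
               0.0367281, 0.0580589, 0.0832518, 0.0244313, 0.0484660,
               0.0862090, 0.0620286, 0.0195027, 0.0384319, 0.0457631,
               0.0695179, 0.0610127, 0.0143859, 0.0352742, 0.0708956)

.exch_matrix <- function(lower) {
  S <- matrix(0, 20, 20, dimnames = list(AA_CODES, AA_CODES))
  S[lower.tri(S)] <- lower
  S <- S + t(S)
  S
}

#' Build a reversible amino-acid substitution model
#'
#' Constructs the normalized instantaneous rate matrix `Q` from an empirical
#' exchangeability matrix `S` and stationary frequencies `pi`
#' (`Q[i,j] = S[i,j] * pi[j]` off-diagonal, diagonal set so rows sum to zero,
#' the whole matrix scaled so the expected substitution rate at stationarity
#' is one), together with `K` discrete-gamma rate categories of shape
#' `alpha`.
#'
#' @param name `"WAG"` (Whelan-Goldman empirical model) or `"Poisson"`
#'   (equal exchangeabilities, uniform frequencies; useful for closed-form
#'   checks).
#' @param alpha Gamma shape parameter (> 0) for among-site rate variation.
#' @param K Number of equal-probability rate categories (>= 1); `K = 1`
#'   means rate homogeneity.
#' @return An object of class `aa_model`: list with elements `name`, `S`,
#'   `pi`, `Q`, `alpha`, `K`, `rates` (category rates averaging 1) and a
#'   cached symmetric eigendecomposition used by [transition_probs()].
#' @examples
#' m <- aa_model("WAG", alpha = 1, K = 4)
#' all.equal(-sum(m$pi * diag(m$Q)), 1)
#' @export
aa_model <- function(name = c("WAG", "Poisson"), alpha = 1, K = 4) {
  name <- as.character(name)[1]
  if (!name %in% c("WAG", "Poisson"))
    stop_pe("model_error", "unknown substitution model '%s'", name)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0)
    stop_pe("model_error", "alpha must be a positive number")
  if (!is.numeric(K) || length(K) != 1 || K < 1 || K != round(K))
    stop_pe("model_error", "K must be a positive integer")
  if (name == "WAG") {
    S <- .exch_matrix(.WAG_EXCH)
    pi <- .WAG_FREQ / sum(.WAG_FREQ)
  } else {
    S <- matrix(1, 20, 20)
    diag(S) <- 0
    dimnames(S) <- list(AA_CODES, AA_CODES)
    pi <- rep(1 / 20, 20)
  }
  names(pi) <- AA_CODES
  Q <- S * rep(pi, each = 20)     # Q[i,j] = S[i,j] * pi[j]
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  Q <- Q / scale
  # Symmetrize with pi^{1/2} for a stable eigendecomposition:
  # B = D^{1/2} Q D^{-1/2} is symmetric for reversible Q.
  sp <- sqrt(pi)
  B <- Q * (sp %o% (1 / sp))
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  model <- list(name = name, S = S, pi = pi, Q = Q,
                alpha = alpha, K = as.integer(K),
                rates = discretize_gamma(alpha, K),
                eig_values = eig$values,
                # P(t) = U exp(L t) Uinv with U = D^{-1/2} V, Uinv = V' D^{1/2}
                eig_U = eig$vectors / sp,
                eig_Uinv = t(eig$vectors) * rep(sp, each = 20))
  class(model) <- "aa_model"
  model
}

#' @export
print.aa_model <- function(x, ...) {
  cat(sprintf("<aa_model %s+G%d, alpha = %g>\n", x$name, x$K, x$alpha))
  invisible(x)
}

#' Discrete-gamma rate categories
#'
#' Mean rates of `K` equal-probability bands of a Gamma(shape = alpha,
#' rate = alpha) distribution (mean 1).  The band mean over quantiles
#' \[q_k, q_{k+1}\] is computed from the incomplete-gamma identity
#' `E[X; a<X<b] = (pgamma(b, alpha+1, alpha) - pgamma(a, alpha+1, alpha))`,
#' divided by the band probability 1/K, and the result is renormalized so
#' the category rates average exactly one.
#'
#' @param alpha Gamma shape (> 0).
#' @param K Number of categories (>= 1).
#' @return Numeric vector of `K` nondecreasing, nonnegative rates with
#'   mean 1.
#' @export
discretize_gamma <- function(alpha, K) {
  if (!is.numeric(alpha) || alpha <= 0)
    stop_pe("model_error", "alpha must be > 0")
  K <- as.integer(K)
  if (K < 1) stop_pe("model_error", "K must be >= 1")
  if (K == 1) return(1)
  q <- qgamma(seq(0, 1, length.out = K + 1), shape = alpha, rate = alpha)
  cum <- pgamma(q, shape = alpha + 1, rate = alpha)
  rates <- (cum[-1] - cum[-(K + 1)]) * K
  rates / mean(rates)
}

#' Transition probability matrix P(t) = exp(Q t r)
#'
#' Computed from the model's cached symmetric eigendecomposition; entries are
#' clamped to \[0, 1\] (eigendecomposition roundoff can produce values a
#' hair outside).
#'
#' @param model An [aa_model()].
#' @param t Branch length in expected substitutions per site (>= 0).
#' @param rate Rate multiplier (for example a gamma category rate).
#' @return 20 x 20 matrix, rows = ancestral state, columns = descendant
#'   state, rows summing to 1.
#' @export
transition_probs <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "aa_model"))
  if (!is.numeric(t) || length(t) != 1 || is.na(t) || t < 0)
    stop_pe("invalid_argument", "branch length t must be a single number >= 0")
  P <- model$eig_U %*% (exp(model$eig_values * t * rate) * model$eig_Uinv)
  P[P < 0] <- 0
  P[P > 1] <- 1
  dimnames(P) <- list(AA_CODES, AA_CODES)
  P
}
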