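# Information-theoretic measures: Shannon capacity and information content,
# compression-based similarity, KL divergence, mutual information.
# Logarithms are base 2 throughout (units of bits).

#' Shannon channel capacity
#'
#' Capacity of an additive-noise channel, \eqn{C = W \log_2(1 + S/N)}:
#' bandwidth W (Hz, or abstract channel uses), signal power S and noise
#' power N in common units. Degradation deceptions raise N; Denial drives
#' W to 0, hence C to 0.
#'
#' @param W Bandwidth, \eqn{\ge 0}.
#' @param S_sig Signal power, \eqn{\ge 0}.
#' @param N_noise Noise power, strictly positive.
#' @return Capacity in bits per second (or bits per channel use).
#' @examples
#' shannon_capacity(1, 3, 1) # 2 bits/s
#' @export
shannon_capacity <- function(W, S_sig, N_noise) {
  stopifnot(W >= 0, S_sig >= 0)
  if (N_noise <= 0) stop("noise power must be strictly positive")
  W * log2(1 + S_sig / N_noise)
}

#' Information content of a message
#'
#' \eqn{I(m) = -\log_2 p(m)}: the less likely the message, the more
#' information its receipt carries.
#'
#' @param p Probability of the message, in (0, 1].
#' @return Information in bits.
#' @export
information_content <- function(p) {
  if (any(p <= 0) || any(p > 1))
    stop("message probability must be in (0, 1]")
  -log2(p)
}

#' Default compressor: gzip at maximum level
#'
#' Maps a byte sequence (raw vector or character scalar) to its compressed
#' size in bytes, via base R's dictionary compressor. Any deterministic
#' size function with the same contract can be substituted.
#'
#' @param x Raw vector or character scalar.
#' @return Compressed size in bytes.
#' @export
gzip_size <- function(x) {
  if (is.character(x)) x <- charToRaw(paste(x, collapse = ""))
  stopifnot(is.raw(x))
  length(memCompress(x, type = "gzip"))
}

#' Compression-based difference and similarity of two messages
#'
#' Approximates information distance with a real compressor:
#' \eqn{D(X, Y) = (K(XY) - \min(K(X), K(Y))) / \max(K(X), K(Y))} and
#' \eqn{S(X, Y) = 1 - D(X, Y)}, where \eqn{K} is the compressed size and
#' \eqn{XY} the concatenation. Values are compressor-relative: identical
#' inputs give D near 0 (up to compressor overhead), unrelated random
#' inputs give D near 1.
#'
#' @param x,y Messages: raw vectors or character scalars; at least one must
#'   be non-empty.
#' @param k Compressor size function (default \code{\link{gzip_size}}).
#' @return List with elements \code{difference} and \code{similarity}.
#' @export
vitanyi_similarity <- function(x, y, k = gzip_size) {
  as_raw <- function(z) if (is.character(z)) charToRaw(paste(z, collapse = "")) else z
  x <- as_raw(x); y <- as_raw(y)
  stopifnot(is.raw(x), is.raw(y))
  if (length(x) == 0 && length(y) == 0)
    stop("at least one message must be non-empty")
  kx <- k(x); ky <- k(y); kxy <- k(c(x, y))
  d <- (kxy - min(kx, ky)) / max(kx, ky)
  list(difference = d, similarity = 1 - d)
}

check_distribution <- function(p, name) {
  if (any(p < 0)) stop(name, " has negative probabilities")
  if (abs(sum(p) - 1) > 1e-12 * max(1, length(p)))
    stop(name, " must sum to 1")
  invisible(p)
}

#' Kullback-Leibler divergence in bits
#'
#' \eqn{D_{KL}(P \| Q) = \sum_x P(x) \log_2(P(x)/Q(x))}, with the
#' convention \eqn{0 \log(0/q) = 0}. Requires absolute continuity: Q must
#' be strictly positive wherever P is. Non-negative; zero iff P = Q.
#' Asymmetric in its arguments.
#'
#' @param p,q Probability vectors over the same finite alphabet.
#' @return Divergence in bits.
#' @export
kl_divergence <- function(p, q) {
  stopifnot(length(p) == length(q))
  check_distribution(p, "p"); check_distribution(q, "q")
  if (any(p > 0 & q == 0))
    stop("q must be strictly positive wherever p is positive")
  i <- p > 0
  sum(p[i] * log2(p[i] / q[i]))
}

#' Mutual information of a discrete joint distribution, in bits
#'
#' \eqn{I(X; Y) = \sum_{x,y} P(x,y) \log_2\{P(x,y) / (P(x) P(y))\}};
#' equivalently the KL divergence of the joint from the product of its
#' marginals. Non-negative; zero iff X and Y are independent.
#'
#' @param joint Matrix of joint probabilities (rows = X, cols = Y),
#'   non-negative, summing to 1.
#' @return Mutual information in bits.
#' @export
mutual_information <- function(joint) {
  stopifnot(is.matrix(joint))
  check_distribution(as.vector(joint), "joint")
  px <- rowSums(joint); py <- colSums(joint)
  prod_marg <- outer(px, py)
  i <- joint > 0
  sum(joint[i] * log2(joint[i] / prod_marg[i]))
}
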