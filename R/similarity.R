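# ---- image similarity metrics ---------------------------------------------

as_values <- function(x) if (inherits(x, "projection_2d")) x$values else as.matrix(x)

#' Normalized cross-correlation between two images
#'
#' Global zero-mean, unit-variance (Pearson) correlation over all pixels,
#' in [-1, 1]. Invariant to affine intensity rescaling of either image.
#'
#' @param a,b \code{projection_2d} objects or matrices of identical shape.
#' @return Scalar in [-1, 1].
#' @export
ncc <- function(a, b) {
  av <- as_values(a); bv <- as_values(b)
  if (!all(dim(av) == dim(bv))) stop("ncc: images must share one shape")
  sa <- stats::sd(av); sb <- stats::sd(bv)
  if (sa == 0 || sb == 0)
    stop("ncc undefined for a zero-variance image")
  mean((av - mean(av)) * (bv - mean(bv))) / (sa * sb) * length(av) / (length(av) - 1)
}

# NCC value plus gradient with respect to image a (b fixed).
ncc_with_grad <- function(av, bv) {
  n <- length(av)
  mu_a <- mean(av); mu_b <- mean(bv)
  sa <- sqrt(mean((av - mu_a)^2)); sb <- sqrt(mean((bv - mu_b)^2))
  if (sa == 0 || sb == 0) stop("ncc undefined for a zero-variance image")
  ah <- (av - mu_a) / sa; bh <- (bv - mu_b) / sb
  val <- mean(ah * bh)
  grad <- (bh - val * ah) / (n * sa)
  list(value = val, grad = grad)
}

#' Soft Dice coefficient and Dice loss
#'
#' \code{dice_coef} is \code{2 sum(ab) / (sum(a) + sum(b))} with additive
#' smoothing \code{eps} in numerator and denominator so that two empty
#' images have Dice 1 (loss 0). \code{dice_loss} is \code{1 - dice_coef}.
#'
#' @param a,b images (binary or soft, identical shape).
#' @param eps additive smoothing.
#' @return Scalar.
#' @export
dice_coef <- function(a, b, eps = 1e-6) {
  av <- as_values(a); bv <- as_values(b)
  if (!all(dim(av) == dim(bv))) stop("dice: images must share one shape")
  (2 * sum(av * bv) + eps) / (sum(av) + sum(bv) + eps)
}

#' @rdname dice_coef
#' @export
dice_loss <- function(a, b, eps = 1e-6) 1 - dice_coef(a, b, eps)

dice_loss_with_grad <- function(av, bv, eps = 1e-6) {
  num <- 2 * sum(av * bv) + eps
  den <- sum(av) + sum(bv) + eps
  list(value = 1 - num / den, grad = -(2 * bv * den - num) / den^2)
}

# ---- mutual information ----------------------------------------------------

scale_unit <- function(v) {
  rng <- range(v)
  if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
}

#' Mutual information between two images
#'
#' Plug-in mutual information (nats) of the joint intensity histogram with
#' \code{bins} x \code{bins} cells over each image's own intensity range.
#' With \code{soft = TRUE}, intensities are assigned to bins with Gaussian
#' weights (sigma = one bin width), giving a differentiable estimate used
#' during optimization; hard binning is used for evaluation. A constant
#' image has zero marginal entropy, hence MI 0.
#'
#' @param a,b \code{projection_2d} objects or matrices of identical shape.
#' @param bins number of histogram bins per image (>= 2).
#' @param soft use Gaussian soft binning.
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(a, b, bins = 32, soft = FALSE) {
  av <- as_values(a); bv <- as_values(b)
  if (!all(dim(av) == dim(bv))) stop("mutual information: images must share one shape")
  stopifnot(bins >= 2)
  if (length(unique(as.numeric(av))) == 1L || length(unique(as.numeric(bv))) == 1L)
    return(0)
  if (soft) return(mi_soft(av, bv, bins)$value)
  ai <- pmin(floor(scale_unit(av) * bins) + 1, bins)
  bi <- pmin(floor(scale_unit(bv) * bins) + 1, bins)
  p <- table(factor(ai, levels = 1:bins), factor(bi, levels = 1:bins)) / length(ai)
  p <- as.matrix(p)
  pk <- rowSums(p); pl <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / outer(pk, pl)[nz]))
}

# Soft-binned MI with gradient with respect to image a (b soft-binned too but
# treated as fixed). Bin weights are a softmax over Gaussian kernels at the
# bin centers, so per-pixel weights sum to one.
mi_soft <- function(av, bv, bins, want_grad = FALSE) {
  n <- length(av)
  an <- scale_unit(av); bn <- scale_unit(bv)
  centers <- (seq_len(bins) - 0.5) / bins
  sigma <- 1 / bins
  Wa <- soft_weights(as.numeric(an), centers, sigma)   # n x bins
  Wb <- soft_weights(as.numeric(bn), centers, sigma)
  p <- crossprod(Wa, Wb) / n                           # bins x bins joint
  pk <- rowSums(p); pl <- colSums(p)
  eps <- 1e-12
  M <- log((p + eps) / (outer(pk, pl) + eps))
  val <- sum(p * M)
  if (!want_grad) return(list(value = val))
  # dval/da_i through the softmax weights of a (range scaling held fixed)
  B <- Wb %*% t(M)                                     # n x bins
  diff <- outer(as.numeric(an), centers, function(x, c) (c - x) / sigma^2)
  s <- rowSums(Wa * diff)
  dWa <- Wa * (diff - s)                               # d w_ik / d a_i
  rng <- range(av)
  scl <- if (rng[2] > rng[1]) 1 / (rng[2] - rng[1]) else 0
  grad <- rowSums(B * dWa) / n * scl
  list(value = val, grad = matrix(grad, nrow(av), ncol(av)))
}

soft_weights <- function(x, centers, sigma) {
  E <- exp(-outer(x, centers, function(x, c) (x - c)^2) / (2 * sigma^2))
  E / rowSums(E)
}
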