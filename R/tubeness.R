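# Gaussian-derivative kernels, sampled from the continuous derivatives of a
# normalized Gaussian; sigma in voxel units. Radius 4*sigma captures the
# support to well below single float precision.
gauss_kernels <- function(sigma) {
  r <- max(3L, as.integer(ceiling(4 * sigma)))
  x <- seq(-r, r)
  g0 <- exp(-x^2 / (2 * sigma^2))
  norm <- sum(g0)
  g0 <- g0 / norm
  g1 <- (-x / sigma^2) * g0
  g2 <- (x^2 / sigma^4 - 1 / sigma^2) * g0
  g2 <- g2 - sum(g2) * g0  # zero DC: constant input must give zero response
  list(g0 = g0, g1 = g1, g2 = g2)
}

conv_sep <- function(arr, kernels_by_axis) {
  d <- dim(arr)
  out <- arr
  for (ax in seq_along(d)) {
    out <- .cpp_conv_axis(as.numeric(out), as.integer(d),
                          kernels_by_axis[[ax]], ax - 1L)
    dim(out) <- d
  }
  out
}

# Hessian of the Gaussian-smoothed image at physical scale sigma_um.
# Returns a list of component arrays in physical units (1/um^2).
hessian_gaussian <- function(img, sigma_um) {
  d <- dim(img$values)
  nd <- length(d)
  sp <- img$spacing
  kl <- lapply(seq_len(nd), function(ax) gauss_kernels(sigma_um / sp[ax]))
  pick <- function(orders) {
    lapply(seq_len(nd), function(ax) {
      k <- kl[[ax]][[c("g0", "g1", "g2")[orders[ax] + 1L]]]
      k / sp[ax]^orders[ax]
    })
  }
  H <- list()
  for (a in seq_len(nd)) {
    for (b in a:nd) {
      orders <- integer(nd)
      orders[a] <- orders[a] + 1L
      orders[b] <- orders[b] + 1L
      H[[paste0("h", a, b)]] <- conv_sep(img$values, pick(orders))
    }
  }
  H
}

# eigenvalues of symmetric 2x2 fields, returned sorted by |value| ascending
eigen2_sym <- function(h11, h22, h12) {
  tr2 <- (h11 + h22) / 2
  disc <- sqrt(((h11 - h22) / 2)^2 + h12^2)
  e1 <- tr2 + disc
  e2 <- tr2 - disc
  lo <- ifelse(abs(e1) <= abs(e2), e1, e2)
  hi <- ifelse(abs(e1) <= abs(e2), e2, e1)
  list(l1 = lo, l2 = hi)
}

# eigenvalues of symmetric 3x3 fields (vectorized trigonometric method),
# sorted by |value| ascending
eigen3_sym <- function(h11, h22, h33, h12, h13, h23) {
  q <- (h11 + h22 + h33) / 3
  p2 <- (h11 - q)^2 + (h22 - q)^2 + (h33 - q)^2 +
    2 * (h12^2 + h13^2 + h23^2)
  p <- sqrt(pmax(p2, 0) / 6)
  ok <- p > 1e-300
  b11 <- (h11 - q); b22 <- (h22 - q); b33 <- (h33 - q)
  detB <- b11 * (b22 * b33 - h23^2) -
    h12 * (h12 * b33 - h23 * h13) +
    h13 * (h12 * h23 - b22 * h13)
  r <- ifelse(ok, detB / (2 * pmax(p, 1e-300)^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  ea <- q + 2 * p * cos(phi)
  ec <- q + 2 * p * cos(phi + 2 * pi / 3)
  eb <- 3 * q - ea - ec
  # sort the triplet by absolute value, elementwise
  aa <- abs(ea); ab <- abs(eb); ac <- abs(ec)
  l1 <- ifelse(aa <= ab & aa <= ac, ea, ifelse(ab <= ac, eb, ec))
  l3 <- ifelse(aa >= ab & aa >= ac, ea, ifelse(ab >= ac, eb, ec))
  l2 <- ea + eb + ec - l1 - l3
  list(l1 = l1, l2 = l2, l3 = l3)
}

#' Tubeness: Hessian eigenvalue vesselness score
#'
#' Computes a ridge-detection score highlighting curvilinear (vessel-like)
#' structures, from the eigenvalues of the Gaussian-smoothed image Hessian
#' at a single physical scale. With eigenvalues sorted
#' \eqn{|\lambda_1| \le |\lambda_2| (\le |\lambda_3|)}, the score is
#' \eqn{-\lambda_2} in 2D when \eqn{\lambda_2 < 0}, and
#' \eqn{\sqrt{\lambda_2\lambda_3}} in 3D when both are negative (Sato-style,
#' bright-on-dark polarity); zero elsewhere. Scores are scale-normalized by
#' \eqn{\sigma^2}. The best single scale is the expected vessel radius.
#'
#' @param img an [image_stack()], finite values.
#' @param sigma physical scale in µm; must be at least one voxel along every
#'   axis.
#' @param polarity `"bright_on_dark"` (default; fluorescence vessels) or
#'   `"dark_on_bright"` (e.g. hypointense vessels on T2*-w MR).
#' @param scales optional vector of physical scales in µm; when given, the
#'   voxelwise maximum of the per-scale normalized scores is returned and
#'   `sigma` is ignored.
#' @return An `image_stack` of nonnegative tubeness scores.
#' @export
tubeness <- function(img, sigma, polarity = c("bright_on_dark",
                                              "dark_on_bright"),
                     scales = NULL) {
  stopifnot_stack(img)
  polarity <- match.arg(polarity)
  if (!is.null(scales)) {
    resp <- lapply(scales, function(s) {
      tubeness(img, s, polarity = polarity)$values
    })
    out <- Reduce(pmax, resp)
    return(image_stack(out, img$spacing))
  }
  if (!all(is.finite(img$values))) stop("non-finite input")
  if (sigma < max(img$spacing)) {
    stop("`sigma` must be at least one voxel in physical units")
  }
  work <- img
  if (polarity == "dark_on_bright") {
    work <- image_stack(-img$values, img$spacing)
  }
  H <- hessian_gaussian(work, sigma)
  nd <- length(dim(img$values))
  if (nd == 2) {
    ev <- eigen2_sym(H$h11, H$h22, H$h12)
    score <- ifelse(ev$l2 < 0, -ev$l2, 0)
  } else {
    ev <- eigen3_sym(H$h11, H$h22, H$h33, H$h12, H$h13, H$h23)
    score <- ifelse(ev$l2 < 0 & ev$l3 < 0, sqrt(pmax(ev$l2 * ev$l3, 0)), 0)
  }
  score <- sigma^2 * score
  dim(score) <- dim(img$values)
  image_stack(score, img$spacing)
}

#' Binarize an image into a vessel mask
#'
#' Thresholds an intensity (typically tubeness) image. The default Otsu
#' method picks the threshold that minimizes intraclass variance of the
#' pooled histogram; the threshold actually applied is always recorded in
#' the returned object so runs are reproducible.
#'
#' @param img an [image_stack()].
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold required when `method = "fixed"`; must lie within the
#'   value range of `img`.
#' @return A `vessel_mask`: list with logical `mask` (`values > threshold`),
#'   `spacing`, `threshold`, and `method`.
#' @export
binarize <- function(img, method = c("otsu", "fixed"), threshold = NULL) {
  stopifnot_stack(img)
  method <- match.arg(method)
  v <- img$values
  rng <- range(v)
  if (method == "otsu") {
    if (diff(rng) == 0) {
      stop("constant image: Otsu threshold undefined; use method = \"fixed\"")
    }
    scaled <- (as.vector(v) - rng[1]) / diff(rng)
    thr01 <- EBImage::otsu(EBImage::Image(matrix(scaled, ncol = 1)),
                           range = c(0, 1), levels = 256L)
    threshold <- thr01 * diff(rng) + rng[1]
  } else {
    if (is.null(threshold)) stop("`threshold` required for method = \"fixed\"")
  }
  m <- v > threshold
  dim(m) <- dim(v)
  structure(list(mask = m, spacing = img$spacing,
                 threshold = as.numeric(threshold), method = method),
            class = "vessel_mask")
}

#' @export
print.vessel_mask <- function(x, ...) {
  cat(sprintf("<vessel_mask> %s, %d foreground voxels (%.2f%%), threshold %.4g (%s)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              100 * mean(x$mask), x$threshold, x$method))
  invisible(x)
}

as_vessel_mask <- function(mask, spacing, threshold = NA_real_,
                           method = "supplied") {
  stopifnot(is.logical(mask), !is.null(dim(mask)))
  structure(list(mask = mask, spacing = spacing, threshold = threshold,
                 method = method), class = "vessel_mask")
}
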