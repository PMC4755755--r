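# Independent oracles and fixture builders used across the suite.
# Oracles are deliberately naive (brute force / fine quadrature / direct
# convolution) and share no code with the implementation paths they check.

# O(F x B) minimum distance from every foreground voxel center to the
# nearest background voxel center, physical units
brute_force_edt <- function(mask, spacing) {
  d <- dim(mask)
  out <- array(0, d)
  fg <- which(mask)
  bg <- which(!mask)
  if (length(fg) == 0 || length(bg) == 0) return(out)
  fc <- sweep(arrayInd(fg, d), 2, spacing, "*")
  bc <- sweep(arrayInd(bg, d), 2, spacing, "*")
  for (i in seq_along(fg)) {
    out[fg[i]] <- sqrt(min(colSums((t(bc) - fc[i, ])^2)))
  }
  out
}

# fine-grid trapezoid quadrature of the exponential convolution
# C_t(t) = K int_0^t C_p(s) exp(-kep (t-s)) ds, factorized so one cumulative
# pass covers all output times; dt in minutes
trapz_tofts <- function(K_trans, v_e, cp_fun, times_min, dt = 1e-5) {
  kep <- K_trans / v_e
  grid <- seq(0, max(times_min), by = dt)
  cp <- cp_fun(grid)
  w <- exp(kep * grid)
  n <- length(grid)
  integ <- c(0, cumsum((cp[-1] * w[-1] + cp[-n] * w[-n]) / 2) * dt)
  ct <- K_trans * exp(-kep * grid) * integ
  stats::approx(grid, ct, xout = times_min, rule = 2)$y
}

biexp_cp <- function(a = c(0.798, 0.956), m = c(0.144, 0.0111), t0_min = 1) {
  function(t_min) {
    tau <- t_min - t0_min
    ifelse(tau < 0, 0,
           a[1] * exp(-m[1] * pmax(tau, 0)) + a[2] * exp(-m[2] * pmax(tau, 0)))
  }
}

# direct (non-separable) Gaussian-derivative convolution at a single 2D
# pixel, reflect boundary; same sampled kernels, independent evaluation
direct_hessian_2d <- function(values, spacing, sigma, at) {
  d <- dim(values)
  k1 <- angioquant:::gauss_kernels(sigma / spacing[1])
  k2 <- angioquant:::gauss_kernels(sigma / spacing[2])
  reflect <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  conv_at <- function(ka, kb) {
    ra <- (length(ka) - 1) / 2
    rb <- (length(kb) - 1) / 2
    acc <- 0
    for (u in -ra:ra) {
      for (v in -rb:rb) {
        acc <- acc + ka[u + ra + 1] * kb[v + rb + 1] *
          values[reflect(at[1] + u, d[1]), reflect(at[2] + v, d[2])]
      }
    }
    acc
  }
  list(h11 = conv_at(k1$g2, k2$g0) / spacing[1]^2,
       h22 = conv_at(k1$g0, k2$g2) / spacing[2]^2,
       h12 = conv_at(k1$g1, k2$g1) / (spacing[1] * spacing[2]))
}

# fabricate a vessel_segment from an arbitrary (possibly non-integer)
# ordered path, for direct tests of the segment statistics
make_path_segment <- function(path, spacing = 1) {
  sp <- if (length(spacing) == 1) rep(spacing, ncol(path)) else spacing
  angioquant:::new_vessel_segment(path, sp)
}

# a straight horizontal segment of given length (spacing 1)
make_straight_segment <- function(length_um, row = 1) {
  make_path_segment(cbind(rep(row, length_um + 1), 0:length_um))
}

# 3D stack of straight tubes along the x (column) axis at radius r_px,
# exact analytic truth; background 10, vessel 100
straight_tube_stack <- function(n_tubes = 10, r_px = 4, shape = c(64, 160, 48),
                                px = 5, seed = 1) {
  set.seed(seed)
  d <- shape
  vol <- array(FALSE, d)
  centers <- NULL
  margin <- r_px + 2
  while (is.null(centers) || nrow(centers) < n_tubes) {
    cand <- c(sample(seq(margin, d[1] - margin), 1),
              sample(seq(margin, d[3] - margin), 1))
    if (!is.null(centers) &&
        any(sqrt(colSums((t(centers) - cand)^2)) < 2 * r_px + 3)) next
    centers <- rbind(centers, cand)
  }
  rows <- matrix(rep(seq_len(d[1]), d[3]), d[1], d[3])
  planes <- matrix(rep(seq_len(d[3]), each = d[1]), d[1], d[3])
  for (t in seq_len(n_tubes)) {
    sect <- (rows - centers[t, 1])^2 + (planes - centers[t, 2])^2 <= r_px^2
    for (j in seq_len(d[2])) vol[, j, ][sect] <- TRUE
  }
  img <- array(10, d)
  img[vol] <- 100
  list(stack = image_stack(img, px), mask = vol,
       truth_radius_um = r_px * px,
       truth_total_length_um = n_tubes * (d[2] - 1) * px)
}

# random blob mask via thresholded smoothed noise (deterministic per seed)
random_blob_mask <- function(d, seed, frac = 0.35) {
  set.seed(seed)
  x <- array(rnorm(prod(d)), d)
  img <- image_stack(x, rep(1, length(d)))
  sm <- angioquant:::conv_sep(img$values, lapply(seq_along(d), function(a) {
    angioquant:::gauss_kernels(1.5)$g0
  }))
  array(sm > stats::quantile(sm, 1 - frac), d)
}

n_components <- function(mask) {
  d <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0) return(0L)
  lut <- array(0L, d)
  lut[idx] <- seq_along(idx)
  coords <- arrayInd(idx, d)
  offs <- angioquant:::neighbor_offsets(length(d))
  visited <- logical(length(idx))
  ncomp <- 0L
  for (s in seq_along(idx)) {
    if (visited[s]) next
    ncomp <- ncomp + 1L
    queue <- s
    visited[s] <- TRUE
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      p <- coords[cur, ]
      for (r in seq_len(nrow(offs))) {
        q <- p + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        id <- if (length(d) == 2) lut[q[1], q[2]] else lut[q[1], q[2], q[3]]
        if (id > 0 && !visited[id]) {
          visited[id] <- TRUE
          queue <- c(queue, id)
        }
      }
    }
  }
  ncomp
}
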