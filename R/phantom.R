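#' Specification for a synthetic tube-network phantom
#'
#' Collects the geometry, intensity and noise parameters of a synthetic
#' vascular phantom emulating a light-sheet stack of bright, tortuous tubes
#' on a dark background. Defaults follow the acquisition scales of the
#' imaging protocol the pipeline targets: 5.16 µm in-plane pixels (0.63x
#' magnification) and 5 µm z-steps for 3D stacks.
#'
#' @param shape integer grid dimensions in voxels (length 2 or 3,
#'   row/column\[/plane\]).
#' @param pixel_size µm per voxel per axis (scalar recycled).
#' @param n_vessels number of primary vessels.
#' @param radius_range vessel radius range in µm `(min, max)`; the minimum
#'   must be at least one voxel.
#' @param tortuosity_target target arc/chord ratio (>= 1) per vessel; a
#'   length-2 vector gives a per-vessel uniform range.
#' @param branching_prob probability per centerline step of spawning a child
#'   branch, in \[0, 1\].
#' @param target_density optional vessel-voxel fraction the phantom must
#'   reach; generation fails explicitly when it exceeds what the requested
#'   vessel count and radii can cover.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param background_level,vessel_level intensity levels.
#' @param min_separation_um minimum clearance between centerlines of
#'   different vessels beyond the sum of their radii (default one voxel);
#'   real vessels do not interpenetrate, and separation keeps ground truth
#'   unambiguous.
#' @param seed integer seed; identical spec + seed reproduces the phantom
#'   bit-exactly.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128, 64), pixel_size = 5,
                         n_vessels = 10, radius_range = c(10, 30),
                         tortuosity_target = 1.1, branching_prob = 0,
                         target_density = NULL, noise_sd = 5,
                         background_level = 10, vessel_level = 100,
                         min_separation_um = NULL, seed = 1L) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (nd < 2 || nd > 3) stop("`shape` must be 2D or 3D")
  pixel_size <- as.numeric(pixel_size)
  if (length(pixel_size) == 1) pixel_size <- rep(pixel_size, nd)
  if (any(pixel_size <= 0)) stop("pixel_size must be positive")
  if (min(radius_range) < min(pixel_size)) {
    stop("radius_range minimum must be at least 1 pixel at this pixel size")
  }
  if (any(tortuosity_target < 1)) stop("tortuosity_target must be >= 1")
  if (branching_prob < 0 || branching_prob > 1) {
    stop("branching_prob must be in [0, 1]")
  }
  if (!is.null(target_density) &&
      (target_density < 0 || target_density > 1)) {
    stop("target_density must be in [0, 1]")
  }
  if (is.null(min_separation_um)) min_separation_um <- max(pixel_size)
  structure(list(shape = shape, pixel_size = pixel_size,
                 n_vessels = as.integer(n_vessels),
                 radius_range = sort(as.numeric(radius_range)),
                 tortuosity_target = as.numeric(tortuosity_target),
                 branching_prob = branching_prob,
                 target_density = target_density,
                 noise_sd = noise_sd, background_level = background_level,
                 vessel_level = vessel_level,
                 min_separation_um = min_separation_um,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# arc/chord ratio of a polyline (rows = points, physical coordinates)
polyline_tortuosity <- function(pts) {
  arc <- sum(sqrt(rowSums(diff(pts)^2)))
  chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
  if (chord == 0) return(Inf)
  arc / chord
}

# moving-average smoothing of a polyline, window w (odd), endpoint-preserving
smooth_polyline <- function(pts, w = 5L) {
  n <- nrow(pts)
  if (n <= w) return(pts)
  out <- pts
  half <- (w - 1L) %/% 2L
  for (ax in seq_len(ncol(pts))) {
    cs <- cumsum(c(0, pts[, ax]))
    i <- (half + 1L):(n - half)
    out[i, ax] <- (cs[i + half + 1L] - cs[i - half]) / w
  }
  out
}

# random-walk centerline: fixed pre-drawn jitter directions scaled by `amp`,
# so tortuosity is a deterministic, near-monotone function of amp and can be
# tuned by bisection. Returns physical-coordinate polyline.
walk_centerline <- function(start, dir0, n_steps, step_um, amp, jitter) {
  nd <- length(start)
  pts <- matrix(0, n_steps + 1L, nd)
  pts[1, ] <- start
  dir <- dir0 / sqrt(sum(dir0^2))
  for (i in seq_len(n_steps)) {
    dir <- dir + amp * jitter[i, ]
    dir <- dir / sqrt(sum(dir^2))
    pts[i + 1L, ] <- pts[i, ] + step_um * dir
  }
  smooth_polyline(pts)
}

# resample a polyline at ~`ds` physical spacing (linear interpolation)
resample_polyline <- function(pts, ds) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  snew <- seq(0, total, by = ds)
  if (snew[length(snew)] < total) snew <- c(snew, total)
  idx <- findInterval(snew, s, rightmost.closed = TRUE)
  idx <- pmin(idx, nrow(pts) - 1L)
  w <- (snew - s[idx]) / pmax(seglen[idx], 1e-300)
  pts[idx, , drop = FALSE] + (pts[idx + 1L, , drop = FALSE] -
                                pts[idx, , drop = FALSE]) * w
}

# minimum distance from each of a set of points to a reference point cloud
min_dist_to_cloud <- function(pts, cloud) {
  if (is.null(cloud) || nrow(cloud) == 0) return(rep(Inf, nrow(pts)))
  vapply(seq_len(nrow(pts)), function(i) {
    sqrt(min(colSums((t(cloud) - pts[i, ])^2)))
  }, numeric(1))
}

# linear indices of voxels whose center lies within `ball` offsets of the
# rounded sample points (candidate superset for the exact distance test)
stamp_candidates <- function(d, pts_px, ball) {
  nd <- length(d)
  lin_all <- integer(0)
  for (p in seq_len(nrow(pts_px))) {
    ctr <- round(pts_px[p, ])
    vox <- ball + rep(ctr, each = nrow(ball))
    ok <- rep(TRUE, nrow(vox))
    for (a in seq_len(nd)) ok <- ok & vox[, a] >= 1 & vox[, a] <= d[a]
    vox <- vox[ok, , drop = FALSE]
    if (nrow(vox) == 0) next
    lin <- vox[, 1]
    if (nd >= 2) lin <- lin + (vox[, 2] - 1L) * d[1]
    if (nd == 3) lin <- lin + (vox[, 3] - 1L) * prod(d[1:2])
    lin_all <- c(lin_all, lin)
  }
  unique(lin_all)
}

# blocked min squared distance from rows of `pts` to rows of `cloud`
min_dist_sq_blocked <- function(pts, cloud, block = 4096L) {
  n <- nrow(pts)
  out <- numeric(n)
  cs <- rowSums(cloud^2)
  tcl <- t(cloud)
  i <- 1L
  while (i <= n) {
    j <- min(i + block - 1L, n)
    P <- pts[i:j, , drop = FALSE]
    D <- outer(rowSums(P^2), cs, "+") - 2 * P %*% tcl
    out[i:j] <- pmax(apply(D, 1, min), 0)
    i <- j + 1L
  }
  out
}

# render one tube exactly: a voxel is vessel iff its center lies within
# r_um (Euclidean, physical units) of the finely sampled centerline
render_tube <- function(vol, px, centerline_um, r_um, step_um) {
  d <- dim(vol)
  nd <- length(d)
  coarse <- resample_polyline(centerline_um, step_um)
  fine <- resample_polyline(centerline_um, step_um / 4)
  coarse_px <- sweep(coarse, 2, px, "/") + 0.5
  rad_px <- ceiling(r_um / px + 1.5)
  offs <- as.matrix(do.call(expand.grid,
                            lapply(rad_px, function(r) seq(-r, r))))
  scale <- 1 / (r_um / px + 1.5)
  ball <- offs[rowSums((offs * rep(scale, each = nrow(offs)))^2) <= 1 + 1e-12,
               , drop = FALSE]
  cand <- stamp_candidates(d, coarse_px, ball)
  if (length(cand) == 0) return(vol)
  coords <- arrayInd(cand, d)
  centers_um <- sweep(coords - 0.5, 2, px, "*")
  d2 <- min_dist_sq_blocked(centers_um, fine)
  vol[cand[d2 <= r_um^2 + 1e-9]] <- TRUE
  vol
}

#' Generate a synthetic tube-network phantom with exact ground truth
#'
#' Builds `n_vessels` smoothed random-walk centerlines whose per-vessel
#' angular jitter is tuned by bisection until the arc/chord ratio is within
#' 5% of the tortuosity target, renders every voxel whose center lies within
#' the vessel radius of the centerline, and adds Gaussian noise. Vessels are
#' placed with rejection sampling so distinct vessels never interpenetrate;
#' with `branching_prob > 0`, child branches spawn from points along a
#' parent and are exempt from the separation rule with respect to their
#' parent. The returned truth records the exact rendered density and the
#' per-vessel centerlines, radii and tortuosities actually realized.
#'
#' @param spec a [phantom_spec()].
#' @return List with `stack` (an [image_stack()]) and `truth` (class
#'   `phantom_truth`: `centerlines_um`, `radii_um`, `per_vessel_tortuosity`,
#'   `length_um`, `mask`, `density`, `n_branches`).
#' @export
generate_tube_network <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_local_seed(spec$seed, {
    d <- spec$shape
    nd <- length(d)
    px <- spec$pixel_size
    extent <- d * px
    vol <- array(FALSE, d)
    step_um <- min(px)

    # feasibility guard for an explicit density target
    if (!is.null(spec$target_density)) {
      max_len <- sqrt(sum(extent^2))
      r_max <- spec$radius_range[2]
      cross <- if (nd == 3) pi * r_max^2 else 2 * r_max
      ach <- spec$n_vessels * (1 + spec$branching_prob * max_len / step_um) *
        max_len * cross / prod(extent)
      if (spec$target_density > ach) {
        stop(sprintf(paste0("impossible density: target %.3f exceeds the ",
                            "achievable packing %.3f for %d vessels of radius ",
                            "<= %.1f um"),
                     spec$target_density, ach, spec$n_vessels, r_max))
      }
    }

    tt <- spec$tortuosity_target
    centerlines <- list()
    radii <- numeric(0)
    placed <- list()   # per-vessel centerline clouds for separation checks
    n_branches <- 0L

    clip_to_interior <- function(pts) {
      # largest run of samples whose voxel centers stay inside the grid
      inb <- rep(TRUE, nrow(pts))
      for (a in seq_len(nd)) {
        inb <- inb & pts[, a] >= 0.5 * px[a] & pts[, a] <= extent[a] - 0.5 * px[a]
      }
      runs <- rle(inb)
      if (!any(runs$values)) return(NULL)
      len_best <- max(runs$lengths[runs$values])
      pos <- which(runs$values & runs$lengths == len_best)[1]
      i0 <- sum(runs$lengths[seq_len(pos - 1)]) + 1L
      pts[i0:(i0 + len_best - 1L), , drop = FALSE]
    }

    make_vessel <- function(existing, r_um, target) {
      # rejection placement: centerline must stay clear of other vessels
      # (per-vessel clearance r_i + r_j + separation); tortuosity is tuned
      # on the clipped (realized) polyline by bisection on the jitter
      # amplitude, with the jitter draws held fixed
      for (attempt in 1:200) {
        margin <- pmin(r_um / px + 2, d / 4)
        start_px <- runif(nd, 1 + margin, d - margin)
        start <- start_px * px
        dir0 <- rnorm(nd)
        n_steps <- as.integer(round(0.9 * max(extent) / step_um))
        # a measurable tube must be long against both the grid and its own
        # radius: stubs a few radii long are all end cap and carry no
        # usable radius or tortuosity signal
        min_samples <- max(10L, as.integer(round(0.25 * max(d))),
                           as.integer(round(6 * r_um / step_um)))
        jitter <- matrix(rnorm(n_steps * nd), n_steps, nd) * 0.15
        realize <- function(amp) {
          clip_to_interior(walk_centerline(start, dir0, n_steps, step_um,
                                           amp, jitter))
        }
        f <- function(amp) {
          p <- realize(amp)
          if (is.null(p) || nrow(p) < min_samples) return(NA_real_)
          polyline_tortuosity(p)
        }
        pts <- NULL
        if (target <= 1 + 1e-9) {
          pts <- realize(0)
          if (is.null(pts) || nrow(pts) < min_samples) next
        } else {
          lo <- 0; hi <- 2
          it <- 0
          fhi <- f(hi)
          while (!is.na(fhi) && fhi < target && it < 8) {
            hi <- hi * 2; it <- it + 1; fhi <- f(hi)
          }
          if (is.na(fhi)) next
          ok <- FALSE
          for (i in 1:50) {
            mid <- (lo + hi) / 2
            v <- f(mid)
            if (is.na(v)) break
            if (abs(v - target) / target <= 0.02) { ok <- TRUE; break }
            if (v < target) lo <- mid else hi <- mid
          }
          if (!ok) next
          pts <- realize(mid)
        }
        if (is.null(pts) || nrow(pts) < min_samples) next
        clear <- TRUE
        for (e in existing) {
          need <- r_um + e$r + spec$min_separation_um
          if (min(min_dist_to_cloud(pts, e$cloud)) < need) {
            clear <- FALSE
            break
          }
        }
        if (!clear) next
        return(pts)
      }
      NULL
    }

    # draw all radii/targets up front and place thick vessels first --
    # the standard packing order, since they need the most clearance
    r_draw <- runif(spec$n_vessels, spec$radius_range[1],
                    spec$radius_range[2])
    t_draw <- if (length(tt) == 2) {
      runif(spec$n_vessels, tt[1], tt[2])
    } else rep(tt, spec$n_vessels)
    ord <- order(-r_draw)
    for (v in seq_len(spec$n_vessels)) {
      r_um <- r_draw[ord[v]]
      target <- t_draw[ord[v]]
      pts <- make_vessel(placed, r_um, target)
      if (is.null(pts)) {
        stop("could not place vessel ", v,
             " without overlap; reduce n_vessels or radius_range")
      }
      centerlines[[length(centerlines) + 1L]] <- pts
      radii <- c(radii, r_um)
      placed[[length(placed) + 1L]] <- list(cloud = pts, r = r_um)

      # optional child branches off this vessel
      if (spec$branching_prob > 0) {
        n_child <- stats::rbinom(1, nrow(pts), spec$branching_prob)
        for (b in seq_len(n_child)) {
          at <- sample.int(nrow(pts) - 1L, 1) + 1L
          dir0 <- pts[at, ] - pts[at - 1L, ] + rnorm(nd) * step_um
          n_steps <- as.integer(round(0.25 * max(extent) / step_um))
          jitter <- matrix(rnorm(n_steps * nd), n_steps, nd) * 0.15
          cpts <- walk_centerline(pts[at, ], dir0, n_steps, step_um, 0.3,
                                  jitter)
          inb <- rep(TRUE, nrow(cpts))
          for (a in seq_len(nd)) {
            inb <- inb & cpts[, a] >= 0.5 * px[a] &
              cpts[, a] <= extent[a] - 0.5 * px[a]
          }
          if (!all(inb)) cpts <- cpts[seq_len(max(1, which(!inb)[1] - 1)), ,
                                      drop = FALSE]
          if (nrow(cpts) < 10) next
          centerlines[[length(centerlines) + 1L]] <- cpts
          radii <- c(radii, r_um * 0.7)
          n_branches <- n_branches + 1L
        }
      }
    }

    # render: voxel centers within r of the (finely resampled) centerline
    for (i in seq_along(centerlines)) {
      vol <- render_tube(vol, px, centerlines[[i]], radii[i], step_um)
    }

    density <- sum(vol) / prod(d)
    if (!is.null(spec$target_density) && density < spec$target_density) {
      stop(sprintf("impossible density: rendered %.4f < target %.4f",
                   density, spec$target_density))
    }

    img <- array(spec$background_level, d)
    img[vol] <- spec$vessel_level
    if (spec$noise_sd > 0) {
      img <- img + array(rnorm(prod(d), 0, spec$noise_sd), d)
    }
    truth <- structure(list(
      centerlines_um = centerlines,
      radii_um = radii,
      per_vessel_tortuosity = vapply(centerlines, polyline_tortuosity,
                                     numeric(1)),
      length_um = vapply(centerlines, function(p) {
        sum(sqrt(rowSums(diff(p)^2)))
      }, numeric(1)),
      mask = vol, density = density, n_branches = n_branches,
      pixel_size = px), class = "phantom_truth")
    list(stack = image_stack(img, px), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("<phantom_truth> %d vessels (%d branches), density %.4f\n",
              length(x$centerlines_um), x$n_branches, x$density))
  invisible(x)
}

#' Generate a pre/post-contrast T2*-like volume pair
#'
#' Emulates the contrast logic of susceptibility-weighted vascular MR:
#' vessels are hypointense only on the post-contrast volume, while
#' microbleed-like dots (spheres of 1-3 px radius) are hypointense on both.
#' A requested dot that would overlap a vessel is relocated
#' deterministically (next draws from the seeded stream) and the relocation
#' count recorded; vessel and microbleed voxel sets are disjoint by
#' construction.
#'
#' @param spec a [phantom_spec()]; vessels are dark on bright here, with
#'   `vessel_level` the hypointense level and `background_level` the tissue
#'   level.
#' @param n_microbleeds number of dot artifacts.
#' @return List with `pre`, `post` (image_stacks) and `truth` (vessel mask,
#'   microbleed mask, density, relocation count).
#' @export
generate_t2star_pair <- function(spec, n_microbleeds = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  net <- generate_tube_network(
    phantom_spec(shape = spec$shape, pixel_size = spec$pixel_size,
                 n_vessels = spec$n_vessels,
                 radius_range = spec$radius_range,
                 tortuosity_target = spec$tortuosity_target,
                 branching_prob = spec$branching_prob,
                 noise_sd = 0, background_level = 0, vessel_level = 1,
                 min_separation_um = spec$min_separation_um,
                 seed = spec$seed))
  vessel_mask <- net$truth$mask
  d <- spec$shape
  nd <- length(d)
  with_local_seed(spec$seed + 1L, {
    bleed_mask <- array(FALSE, d)
    relocated <- 0L
    for (b in seq_len(n_microbleeds)) {
      for (attempt in 1:200) {
        r_px <- sample(1:3, 1)
        ctr <- round(runif(nd, 1 + r_px, d - r_px))
        offs <- as.matrix(do.call(expand.grid,
                                  lapply(seq_len(nd),
                                         function(a) seq(-r_px, r_px))))
        offs <- offs[rowSums(offs^2) <= r_px^2 + 1e-9, , drop = FALSE]
        vox <- offs + rep(ctr, each = nrow(offs))
        lin <- vox[, 1] + (vox[, 2] - 1L) * d[1]
        if (nd == 3) lin <- lin + (vox[, 3] - 1L) * prod(d[1:2])
        if (any(vessel_mask[lin]) || any(bleed_mask[lin])) {
          relocated <- relocated + 1L
          next
        }
        bleed_mask[lin] <- TRUE
        break
      }
    }
    bg <- spec$background_level
    lev <- spec$vessel_level
    pre <- array(bg, d)
    pre[bleed_mask] <- lev
    post <- array(bg, d)
    post[vessel_mask] <- lev
    post[bleed_mask] <- lev
    if (spec$noise_sd > 0) {
      pre <- pre + array(rnorm(prod(d), 0, spec$noise_sd), d)
      post <- post + array(rnorm(prod(d), 0, spec$noise_sd), d)
    }
    truth <- structure(list(
      vessel_mask = vessel_mask, microbleed_mask = bleed_mask,
      density = sum(vessel_mask) / prod(d),
      n_relocated = relocated,
      centerlines_um = net$truth$centerlines_um,
      radii_um = net$truth$radii_um), class = "phantom_truth")
    list(pre = image_stack(pre, spec$pixel_size),
         post = image_stack(post, spec$pixel_size),
         truth = truth)
  })
}

#' Simulation parameters for a DCE signal-time series
#'
#' @param K_trans transfer constant in 1/min (>= 0).
#' @param v_e extravascular extracellular volume fraction in (0, 1\].
#' @param time_grid acquisition times in seconds, strictly increasing;
#'   default 2 s spacing over 10 min (300 frames).
#' @param baseline baseline signal (a.u.).
#' @param enhancement_scale signal change per mM of tissue contrast agent.
#' @param noise_sd Gaussian signal noise SD (a.u.).
#' @param seed integer seed.
#' @return Object of class `dce_sim_params`.
#' @export
dce_sim_params <- function(K_trans = 0.05, v_e = 0.2,
                           time_grid = seq(0, 598, by = 2),
                           baseline = 100, enhancement_scale = 50,
                           noise_sd = 0, seed = 1L) {
  if (K_trans < 0) stop("K_trans must be >= 0")
  if (v_e <= 0 || v_e > 1) stop("v_e must be in (0, 1]")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  structure(list(K_trans = K_trans, v_e = v_e,
                 time_grid = as.numeric(time_grid), baseline = baseline,
                 enhancement_scale = enhancement_scale, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "dce_sim_params")
}

#' Simulate a two-ROI DCE series with known kinetics
#'
#' The tumor ROI follows the Tofts forward model driven by the supplied
#' arterial input function; the contralateral ROI is flat baseline. Both get
#' independent Gaussian noise.
#'
#' @param params a [dce_sim_params()].
#' @param aif an [aif_biexponential()] model.
#' @return A `dce_series`: list with `times_s`, `tumor_signal`,
#'   `contralateral_signal` and `kinetic_truth`.
#' @export
generate_dce_series <- function(params, aif) {
  stopifnot(inherits(params, "dce_sim_params"))
  ct <- tofts_forward(params$K_trans, params$v_e, aif, params$time_grid)
  n <- length(params$time_grid)
  with_local_seed(params$seed, {
    noise_t <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else
      numeric(n)
    noise_c <- if (params$noise_sd > 0) rnorm(n, 0, params$noise_sd) else
      numeric(n)
    structure(list(
      times_s = params$time_grid,
      tumor_signal = params$baseline + params$enhancement_scale * ct + noise_t,
      contralateral_signal = params$baseline + noise_c,
      kinetic_truth = list(K_trans = params$K_trans, v_e = params$v_e)),
      class = "dce_series")
  })
}

#' @export
print.dce_series <- function(x, ...) {
  cat(sprintf("<dce_series> %d frames, %.0f s span\n", length(x$times_s),
              diff(range(x$times_s))))
  invisible(x)
}

#' Write phantom ground truth as JSON + CSV
#'
#' @param truth a `phantom_truth`.
#' @param json_path,csv_path output paths (either may be `NULL`).
#' @return Invisibly, the per-vessel data.frame.
#' @export
write_phantom_truth <- function(truth, json_path = NULL, csv_path = NULL) {
  df <- data.frame(id = seq_along(truth$centerlines_um),
                   length_um = truth$length_um,
                   mean_radius_um = truth$radii_um,
                   tortuosity = truth$per_vessel_tortuosity)
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(density = truth$density,
                              n_vessels = nrow(df), vessels = df),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(df)
}
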