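#' Skeletonize a vessel mask
#'
#' Reduces a binary mask to a one-voxel-thick centerline by sequential
#' topology-preserving thinning (8-connected foreground / 4-connected
#' background in 2D; 26/6 in 3D, using the standard simple-point
#' characterization). Curve endpoints are preserved, so isolated voxels and
#' line ends survive; connected-component count of the mask is preserved.
#'
#' @param mask a `vessel_mask` (see [binarize()]) or a logical array.
#' @param spacing voxel spacing in µm, required when `mask` is a bare array.
#' @return A `skeleton`: list with logical `mask`, `spacing`, and the
#'   neighborhood `connectivity` used (8 in 2D, 26 in 3D). An empty input
#'   yields an empty skeleton.
#' @export
skeletonize_mask <- function(mask, spacing = NULL) {
  m <- resolve_mask(mask, spacing)
  d <- dim(m$mask)
  thin <- .cpp_thin(as.logical(m$mask), as.integer(d))
  dim(thin) <- d
  structure(list(mask = thin, spacing = m$spacing,
                 connectivity = if (length(d) == 2) 8L else 26L),
            class = "skeleton")
}

#' @export
print.skeleton <- function(x, ...) {
  cat(sprintf("<skeleton> %s, %d centerline voxels (%d-connectivity)\n",
              paste(dim(x$mask), collapse = " x "), sum(x$mask),
              x$connectivity))
  invisible(x)
}

resolve_mask <- function(mask, spacing = NULL) {
  if (inherits(mask, "vessel_mask")) return(mask)
  if (is.logical(mask) && !is.null(dim(mask))) {
    nd <- length(dim(mask))
    if (is.null(spacing)) spacing <- 1
    spacing <- as.numeric(spacing)
    if (length(spacing) == 1) spacing <- rep(spacing, nd)
    return(as_vessel_mask(mask, spacing))
  }
  stop("expected a `vessel_mask` or a logical array")
}

# all 8- / 26-neighborhood integer offsets for an array of dimension `d`
neighbor_offsets <- function(nd) {
  if (nd == 2) {
    g <- expand.grid(di = -1:1, dj = -1:1)
  } else {
    g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  }
  g <- as.matrix(g)
  g[rowSums(g != 0) > 0, , drop = FALSE]
}

# count of TRUE neighbors (full 8/26 neighborhood) for every voxel
neighbor_count <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  offs <- neighbor_offsets(nd)
  cnt <- array(0L, d)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    idx_dst <- lapply(seq_len(nd), function(a) {
      seq.int(max(1L, 1L + o[a]), min(d[a], d[a] + o[a]))
    })
    idx_src <- lapply(seq_len(nd), function(a) idx_dst[[a]] - o[a])
    if (nd == 2) {
      cnt[idx_dst[[1]], idx_dst[[2]]] <-
        cnt[idx_dst[[1]], idx_dst[[2]]] +
        mask[idx_src[[1]], idx_src[[2]]]
    } else {
      cnt[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
        cnt[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] +
        mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    }
  }
  cnt
}

#' Branch points of a skeleton
#'
#' A branch point is a skeleton voxel with more than two skeleton neighbors
#' in the full 8- (2D) or 26- (3D) neighborhood. Subtracting them splits the
#' vascular network into simple segments.
#'
#' @param skel a `skeleton` from [skeletonize_mask()].
#' @return Logical array marking branch-point voxels.
#' @export
branch_points <- function(skel) {
  stopifnot(inherits(skel, "skeleton"))
  cnt <- neighbor_count(skel$mask)
  skel$mask & (cnt > 2L)
}

# step length in physical units between consecutive path voxels
step_lengths <- function(path, spacing) {
  if (nrow(path) < 2) return(numeric(0))
  dif <- diff(path)
  sqrt(rowSums((dif * rep(spacing, each = nrow(dif)))^2))
}

new_vessel_segment <- function(path, spacing) {
  L <- sum(step_lengths(path, spacing))
  ends <- path[c(1, nrow(path)), , drop = FALSE]
  chord <- sqrt(sum(((ends[2, ] - ends[1, ]) * spacing)^2))
  tort <- if (chord > 0) L / chord else 1.0
  structure(list(path = path, n_pixels = nrow(path), length_um = L,
                 chord_um = chord, tortuosity = tort, is_loop = FALSE,
                 endpoints = ends, radii_um = NULL,
                 mean_radius_um = NA_real_, spacing = spacing),
            class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat(sprintf("<vessel_segment> %d px, length %.2f um, tortuosity %s%s\n",
              x$n_pixels, x$length_um,
              if (is.na(x$tortuosity)) "NA" else sprintf("%.4f", x$tortuosity),
              if (x$is_loop) " (loop)" else ""))
  invisible(x)
}

#' Split a skeleton into vessel segments at branch points
#'
#' Removes branch points (voxels with more than two skeleton neighbors) and
#' orders each remaining connected component end-to-end into a centerline
#' path. Segment length is the Euclidean step sum in physical units (a
#' diagonal step counts \eqn{\sqrt{2}}, a 3D space diagonal \eqn{\sqrt{3}}
#' times the spacing); tortuosity is length divided by the Euclidean
#' distance between the endpoints. Cyclic components (loops) are retained
#' with the path started at the lowest coordinate tuple, but their
#' tortuosity is undefined and flagged.
#'
#' @param skel a `skeleton` from [skeletonize_mask()].
#' @param spacing optional spacing override in µm (defaults to the
#'   skeleton's own spacing).
#' @return List of `vessel_segment` objects.
#' @export
split_segments <- function(skel, spacing = NULL) {
  stopifnot(inherits(skel, "skeleton"))
  spacing <- if (is.null(spacing)) skel$spacing else {
    sp <- as.numeric(spacing)
    if (length(sp) == 1) rep(sp, length(dim(skel$mask))) else sp
  }
  d <- dim(skel$mask)
  nd <- length(d)
  keep <- skel$mask & !branch_points(skel)
  idx <- which(keep)
  if (length(idx) == 0) return(list())

  coords <- arrayInd(idx, d)
  lut <- array(0L, d)
  lut[idx] <- seq_along(idx)
  offs <- neighbor_offsets(nd)

  nbrs_of <- function(v) {
    p <- coords[v, ]
    out <- integer(0)
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1L) || any(q > d)) next
      id <- if (nd == 2) lut[q[1], q[2]] else lut[q[1], q[2], q[3]]
      if (id > 0L) out <- c(out, id)
    }
    out
  }
  adj <- lapply(seq_along(idx), nbrs_of)
  deg <- lengths(adj)

  visited <- logical(length(idx))
  segments <- list()
  # deterministic: scan voxels in linear-index order; endpoints first so that
  # open paths are walked end-to-end, then remaining (loop) components
  order_pass <- c(which(deg <= 1L), which(deg > 1L))
  for (v0 in order_pass) {
    if (visited[v0]) next
    path <- integer(0)
    prev <- 0L
    cur <- v0
    repeat {
      visited[cur] <- TRUE
      path <- c(path, cur)
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!visited[nxt]]
      if (length(nxt) == 0) break
      prev <- cur
      cur <- min(nxt)  # deterministic tie-break (paths have <= 1 new nbr)
    }
    pm <- coords[path, , drop = FALSE]
    closed <- deg[v0] > 1L && length(path) > 2 &&
      (path[1] %in% adj[[path[length(path)]]])
    seg <- new_vessel_segment(pm, spacing)
    if (closed) {
      seg$is_loop <- TRUE
      seg$tortuosity <- NA_real_
      # close the ring in the reported length
      seg$length_um <- seg$length_um +
        sqrt(sum(((pm[1, ] - pm[nrow(pm), ]) * spacing)^2))
      seg$chord_um <- 0
    }
    segments[[length(segments) + 1L]] <- seg
  }
  segments
}

#' Filter segments by the mean-minus-standard-error length rule
#'
#' Keeps a segment when its length exceeds the mean of the segment-length
#' distribution minus its standard error (sample SD divided by
#' \eqn{\sqrt{n}}), discarding the very short cross-section stubs that
#' otherwise bias diameter statistics. With a single segment the filter
#' keeps it; when all lengths are equal (SD = 0) equality is retained, since
#' a strict rule would discard everything.
#'
#' @param segments list of `vessel_segment`.
#' @param spread `"sem"` (default) or `"sd"`: which spread statistic to
#'   subtract from the mean.
#' @return The kept sublist, with attribute `"threshold"` recording the
#'   length cutoff in µm.
#' @export
filter_segments_by_length <- function(segments, spread = c("sem", "sd")) {
  spread <- match.arg(spread)
  if (length(segments) == 0) return(segments)
  L <- vapply(segments, function(s) s$length_um, numeric(1))
  n <- length(L)
  if (n == 1) {
    out <- segments
    attr(out, "threshold") <- mean(L)
    return(out)
  }
  s <- sd(L)
  thr <- mean(L) - if (spread == "sem") s / sqrt(n) else s
  kept <- if (s == 0) L >= thr else L > thr
  out <- segments[kept]
  attr(out, "threshold") <- thr
  out
}
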