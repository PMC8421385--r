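# zero-padded shift for binary morphology
shift0 <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- m[rs[rok], cs[cok]]
  out
}

neighbor_count <- function(b) {
  shift0(b, -1, 0) + shift0(b, 1, 0) + shift0(b, 0, -1) + shift0(b, 0, 1) +
    shift0(b, -1, -1) + shift0(b, -1, 1) + shift0(b, 1, -1) + shift0(b, 1, 1)
}

#' Binary skeletonization by Zhang-Suen thinning
#'
#' Iteratively peels boundary pixels from a binary foreground until a
#' one-pixel-wide, 8-connected skeleton remains. Written in vectorized
#' whole-image passes; each pass costs a handful of matrix shifts, and the
#' number of passes is bounded by half the maximal object width.
#'
#' @param binary logical or 0/1 matrix.
#' @return logical matrix of the same shape containing the skeleton.
#' @export
skeletonize <- function(binary) {
  b <- matrix(as.integer(binary > 0), nrow(binary), ncol(binary))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      # clockwise neighbors starting north (row - 1)
      p2 <- shift0(b, -1, 0); p3 <- shift0(b, -1, 1); p4 <- shift0(b, 0, 1)
      p5 <- shift0(b, 1, 1);  p6 <- shift0(b, 1, 0);  p7 <- shift0(b, 1, -1)
      p8 <- shift0(b, 0, -1); p9 <- shift0(b, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { b[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  b == 1L
}

# Rutovitz crossing number: count of 0->1 transitions around each pixel.
# 1 = path end, 2 = interior path pixel, >= 3 = branch/junction. More robust
# than the raw neighbor count, which flags staircase pixels of diagonal
# skeleton runs as spurious junctions.
crossing_number <- function(skel) {
  b <- matrix(as.integer(skel), nrow(skel))
  p2 <- shift0(b, -1, 0); p3 <- shift0(b, -1, 1); p4 <- shift0(b, 0, 1)
  p5 <- shift0(b, 1, 1);  p6 <- shift0(b, 1, 0);  p7 <- shift0(b, 1, -1)
  p8 <- shift0(b, 0, -1); p9 <- shift0(b, -1, -1)
  (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
}

# indices of 8-neighbors of (r, c) that are TRUE in skel
nb8 <- function(skel, r, c) {
  nr <- nrow(skel); nc <- ncol(skel)
  out <- matrix(0L, 0, 2)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && skel[rr, cc])
      out <- rbind(out, c(rr, cc))
  }
  out
}

# remove skeleton side-branches shorter than min_len that terminate at a junction
prune_spurs <- function(skel, min_len) {
  repeat {
    cn <- crossing_number(skel)
    ends <- which(skel & cn == 1, arr.ind = TRUE)
    removed <- FALSE
    if (nrow(ends)) {
      for (i in seq_len(nrow(ends))) {
        r <- ends[i, 1]; c <- ends[i, 2]
        if (!skel[r, c] || cn[r, c] != 1) next
        path <- list(c(r, c)); len <- 0
        prev <- c(-1L, -1L)
        repeat {
          nbs <- nb8(skel, r, c)
          nbs <- nbs[!(nbs[, 1] == prev[1] & nbs[, 2] == prev[2]), , drop = FALSE]
          if (nrow(nbs) == 0L) { hit_junction <- FALSE; break }   # reached the far end
          if (nrow(nbs) > 1L) {                                    # prefer orthogonal steps
            d <- abs(nbs[, 1] - r) + abs(nbs[, 2] - c)
            nbs <- nbs[order(d), , drop = FALSE]
          }
          if (cn[nbs[1, 1], nbs[1, 2]] >= 3) { hit_junction <- TRUE; break }
          prev <- c(r, c); r <- nbs[1, 1]; c <- nbs[1, 2]
          len <- len + sqrt(sum((c(r, c) - prev)^2))
          path[[length(path) + 1L]] <- c(r, c)
          if (len >= min_len) { hit_junction <- FALSE; break }
        }
        if (hit_junction && len < min_len) {
          for (pxy in path) skel[pxy[1], pxy[2]] <- FALSE
          removed <- TRUE
        }
      }
    }
    if (!removed) break
  }
  skel
}

# label 8-connected components of a sparse logical matrix; returns list of
# n x 2 (row, col) index matrices
label_components <- function(skel) {
  lab <- matrix(0L, nrow(skel), ncol(skel))
  comps <- list()
  idx <- which(skel, arr.ind = TRUE)
  if (!nrow(idx)) return(comps)
  for (k in seq_len(nrow(idx))) {
    r0 <- idx[k, 1]; c0 <- idx[k, 2]
    if (lab[r0, c0] != 0L) next
    id <- length(comps) + 1L
    queue <- matrix(c(r0, c0), 1, 2)
    lab[r0, c0] <- id
    members <- queue
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]; queue <- queue[-1, , drop = FALSE]
      nbs <- nb8(skel, cur[1], cur[2])
      if (nrow(nbs)) {
        new <- nbs[lab[nbs] == 0L, , drop = FALSE]
        if (nrow(new)) {
          lab[new] <- id
          queue <- rbind(queue, new)
          members <- rbind(members, new)
        }
      }
    }
    comps[[id]] <- members
  }
  comps
}

# order a simple-path component from an endpoint; returns ordered (row, col)
trace_path <- function(members) {
  n <- nrow(members)
  if (n == 1L) return(members)
  key <- paste(members[, 1], members[, 2])
  pos <- seq_len(n); names(pos) <- key
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    d <- abs(members[, 1] - members[i, 1]) <= 1 & abs(members[, 2] - members[i, 2]) <= 1
    d[i] <- FALSE
    adj[[i]] <- which(d)
  }
  degs <- lengths(adj)
  start <- if (any(degs == 1)) which(degs == 1)[1] else 1L
  visited <- logical(n)
  order_idx <- integer(0)
  cur <- start
  repeat {
    visited[cur] <- TRUE
    order_idx <- c(order_idx, cur)
    nxt <- adj[[cur]][!visited[adj[[cur]]]]
    if (!length(nxt)) break
    if (length(nxt) > 1L) {  # prefer orthogonal continuation over diagonal
      d <- abs(members[nxt, 1] - members[cur, 1]) + abs(members[nxt, 2] - members[cur, 2])
      nxt <- nxt[order(d)]
    }
    cur <- nxt[1]
  }
  members[order_idx, , drop = FALSE]
}

# arc length of an ordered pixel path, measured on a subsampled polyline so
# the 8-connected staircase does not inflate the estimate (a diagonal run
# traversed pixel-by-pixel is up to 8% longer than the straight chord)
path_arc_length <- function(path, step = 4L) {
  n <- nrow(path)
  if (n < 2L) return(0)
  idx <- unique(c(seq(1L, n, by = step), n))
  pts <- path[idx, , drop = FALSE]
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

#' Trace individual fibers from a fiber-stained image
#'
#' Simplified individual-fiber extraction: Gaussian smoothing, Otsu (or
#' fixed) thresholding, Zhang-Suen skeletonization, pruning of side branches
#' shorter than `min_fiber_len_px`, splitting of the skeleton at junction
#' pixels (>= 3 skeleton neighbors), and tracing of each remaining path as one
#' fiber. Per-fiber width is the mean of `2 d - 1` over centerline pixels,
#' where `d` is the Euclidean distance transform of the foreground (the
#' medial-axis width of a ribbon). No linking of fibers across crossings is
#' attempted.
#'
#' @param image an [image2d()] or numeric matrix.
#' @param smooth_sigma Gaussian smoothing sigma (px); 0 disables smoothing.
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold_value intensity threshold when `threshold_method="fixed"`.
#' @param min_fiber_len_px minimum traced fiber arc length kept (px), >= 2.
#' @param junction_break break the skeleton at junction pixels (default TRUE).
#' @return a `fiber_set`: list with `fibers` (each with `centerline` as an
#'   n x 2 `(x, y)` matrix, `length`, `width`, `angle`, `straightness`),
#'   `image_size`, `centerline_raster`, `n_fibers`.
#' @export
extract_fibers <- function(image, smooth_sigma = 1,
                           threshold_method = c("otsu", "fixed"),
                           threshold_value = NULL,
                           min_fiber_len_px = 10, junction_break = TRUE) {
  threshold_method <- match.arg(threshold_method)
  image <- as_image2d(image)
  if (min_fiber_len_px < 2) stopf("`min_fiber_len_px` must be >= 2")
  px <- image$pixels
  sm <- if (smooth_sigma > 0) EBImage::gblur(px, sigma = smooth_sigma) else px
  thr <- if (threshold_method == "otsu") {
    if (max(sm) - min(sm) < 1e-12) Inf  # flat image: no foreground
    else EBImage::otsu(sm, range = range(sm))
  } else {
    if (is.null(threshold_value)) stopf("`threshold_value` required for fixed thresholding")
    threshold_value
  }
  fg <- sm > thr
  if (!is.null(image$mask)) fg <- fg & image$mask
  empty <- structure(list(fibers = list(), image_size = dim(px),
                          centerline_raster = matrix(FALSE, nrow(px), ncol(px)),
                          n_fibers = 0L, threshold = thr),
                     class = "fiber_set")
  if (!any(fg)) return(empty)

  skel <- skeletonize(fg)
  skel <- prune_spurs(skel, min_fiber_len_px)
  if (!any(skel)) return(empty)
  if (junction_break) {
    cn <- crossing_number(skel)
    skel[skel & cn >= 3] <- FALSE
  }
  if (!any(skel)) return(empty)

  dmap <- EBImage::distmap(fg)
  comps <- label_components(skel)
  fibers <- list()
  raster <- matrix(FALSE, nrow(px), ncol(px))
  for (m in comps) {
    path <- trace_path(m)
    if (nrow(path) < 2L) next
    arc <- path_arc_length(path)
    if (arc < min_fiber_len_px) next
    chord <- sqrt(sum((path[nrow(path), ] - path[1, ])^2))
    # centerline in (x, y) = (col, row) convention
    centerline <- cbind(x = path[, 2], y = path[, 1])
    dxy <- centerline[nrow(centerline), ] - centerline[1, ]
    fibers[[length(fibers) + 1L]] <- list(
      centerline = centerline,
      length = arc,
      width = mean(2 * dmap[m] - 1),
      angle = wrap_axial(atan2(dxy[2], dxy[1])),
      straightness = min(chord / arc, 1))
    raster[m] <- TRUE
  }
  structure(list(fibers = fibers, image_size = dim(px),
                 centerline_raster = raster, n_fibers = length(fibers),
                 threshold = thr),
            class = "fiber_set")
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers in %d x %d px image\n",
              x$n_fibers, x$image_size[1], x$image_size[2]))
  invisible(x)
}

#' Per-fiber metrics table
#'
#' @param x a `fiber_set`.
#' @param ... unused.
#' @return data.frame with one row per fiber: `fiber_id`, `length`, `width`,
#'   `angle`, `straightness`, `curvature` (1 - straightness).
#' @export
as.data.frame.fiber_set <- function(x, ...) {
  if (x$n_fibers == 0L)
    return(data.frame(fiber_id = integer(0), length = numeric(0),
                      width = numeric(0), angle = numeric(0),
                      straightness = numeric(0), curvature = numeric(0)))
  data.frame(fiber_id = seq_len(x$n_fibers),
             length = vapply(x$fibers, `[[`, numeric(1), "length"),
             width = vapply(x$fibers, `[[`, numeric(1), "width"),
             angle = vapply(x$fibers, `[[`, numeric(1), "angle"),
             straightness = vapply(x$fibers, `[[`, numeric(1), "straightness"),
             curvature = 1 - vapply(x$fibers, `[[`, numeric(1), "straightness"))
}

#' Mean fiber-centerline density over a regular box tiling
#'
#' Tiles the image into `box_px` x `box_px` boxes (edge boxes may be smaller)
#' and returns the mean fraction of centerline pixels per box. Boxes with no
#' mask overlap are excluded when a mask is supplied.
#'
#' @param fibers a `fiber_set`.
#' @param box_px box side in pixels, >= 2.
#' @param mask optional logical matrix (TRUE = tissue).
#' @return mean centerline-pixel fraction over boxes, in `[0, 1]`.
#' @export
box_density <- function(fibers, box_px = 32L, mask = NULL) {
  if (box_px < 2L) stopf("`box_px` must be >= 2")
  r <- fibers$centerline_raster
  nr <- nrow(r); nc <- ncol(r)
  if (box_px > nr || box_px > nc) {
    warnf("box (%d px) larger than image; using a single box", box_px)
    return(mean(r))
  }
  rb <- ceiling(seq_len(nr) / box_px); cb <- ceiling(seq_len(nc) / box_px)
  bid <- (rep(rb, times = nc) - 1L) * max(cb) + rep(cb, each = nr)
  num <- rowsum(as.vector(r) * 1, bid)[, 1]
  den <- rowsum(rep(1, length(bid)), bid)[, 1]
  keep <- rep(TRUE, length(num))
  if (!is.null(mask)) keep <- rowsum(as.vector(mask) * 1, bid)[, 1] > 0
  mean(num[keep] / den[keep])
}

# mean local centerline fraction in window_px windows centered on centerline
# pixels (density local to the fibers, as distinct from the global tiling)
#' Localized fiber density
#'
#' Mean centerline-pixel fraction inside a `window_px` sliding window,
#' averaged over windows centered on centerline pixels.
#'
#' @param fibers a `fiber_set`.
#' @param window_px window side in pixels.
#' @return localized density in `[0, 1]`; 0 when the set is empty.
#' @export
localized_density <- function(fibers, window_px = 32L) {
  r <- fibers$centerline_raster
  if (!any(r)) return(0)
  nr <- nrow(r); nc <- ncol(r)
  h <- max(1L, window_px %/% 2L)
  # integral image for O(1) box sums
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1, -1] <- t(apply(apply(r * 1, 2, cumsum), 1, cumsum))
  idx <- which(r, arr.ind = TRUE)
  r1 <- pmax(idx[, 1] - h, 1L); r2 <- pmin(idx[, 1] + h, nr)
  c1 <- pmax(idx[, 2] - h, 1L); c2 <- pmin(idx[, 2] + h, nc)
  sums <- S[cbind(r2 + 1L, c2 + 1L)] - S[cbind(r1, c2 + 1L)] -
    S[cbind(r2 + 1L, c1)] + S[cbind(r1, c1)]
  areas <- (r2 - r1 + 1) * (c2 - c1 + 1)
  mean(sums / areas)
}

#' Summarize a fiber set into per-sample metrics
#'
#' Per-sample averages of the per-fiber morphometrics plus the density
#' metrics, as used for downstream group statistics. `feature_number` is the
#' fiber count per unit image area (per px^2, or per physical area when
#' `pixel_size` is given, in which case lengths and widths are also scaled).
#'
#' @param fibers a `fiber_set` from [extract_fibers()].
#' @param image_area image area; defaults to the pixel area of the source.
#' @param pixel_size optional physical pixel size.
#' @param box_px box/window side for the density metrics.
#' @param mask optional mask forwarded to [box_density()].
#' @return a `fiber_metrics_summary` list; means are `NA` (and `empty` is
#'   TRUE) when the set has no fibers.
#' @export
fiber_metrics <- function(fibers, image_area = NULL, pixel_size = NULL,
                          box_px = 32L, mask = NULL) {
  area_px <- prod(fibers$image_size)
  image_area <- image_area %||% area_px
  if (image_area <= 0) stopf("`image_area` must be > 0")
  ps <- pixel_size %||% 1
  df <- as.data.frame(fibers)
  n <- nrow(df)
  area <- image_area * ps^2
  s <- function(f, v) if (n > 0) f(v) else NA_real_
  lens <- df$length * ps; wids <- df$width * ps
  structure(list(
    n_fibers = n,
    empty = n == 0L,
    feature_number = n / area,
    length_mean = s(mean, lens), length_sd = if (n > 1) sd(lens) else NA_real_,
    length_median = s(stats::median, lens), length_max = s(max, lens),
    length_cv = if (n > 1 && mean(lens) > 0) sd(lens) / mean(lens) else NA_real_,
    width_mean = s(mean, wids), width_sd = if (n > 1) sd(wids) else NA_real_,
    straightness_mean = s(mean, df$straightness),
    straightness_sd = if (n > 1) sd(df$straightness) else NA_real_,
    curvature_mean = s(mean, df$curvature),
    angles = df$angle,
    fiber_mvl = if (n > 0) sqrt(mean(cos(2 * df$angle))^2 + mean(sin(2 * df$angle))^2) else NA_real_,
    fiber_angle_kurtosis = if (n >= 4)
      tryCatch(angle_kurtosis(df$angle, degenerate = "inf"), error = function(e) NA_real_)
      else NA_real_,
    box_density = box_density(fibers, box_px = box_px, mask = mask),
    localized_density = localized_density(fibers, window_px = box_px),
    total_length_density = if (n > 0) sum(lens) / area else 0,
    aspect_ratio_mean = s(mean, ifelse(wids > 0, lens / wids, NA_real_)),
    image_area = area), class = "fiber_metrics_summary")
}

#' Write a fiber set to CSV
#'
#' Two files: centerlines (`fiber_id, vertex_idx, x, y`) and per-fiber
#' metrics.
#'
#' @param fibers a `fiber_set`.
#' @param centerline_path,metrics_path output CSV paths (either may be NULL).
#' @return invisibly, a list of the written paths.
#' @export
write_fibers_csv <- function(fibers, centerline_path = NULL, metrics_path = NULL) {
  if (!is.null(centerline_path)) {
    rows <- lapply(seq_along(fibers$fibers), function(i) {
      cl <- fibers$fibers[[i]]$centerline
      data.frame(fiber_id = i, vertex_idx = seq_len(nrow(cl)),
                 x = cl[, 1], y = cl[, 2])
    })
    utils::write.csv(if (length(rows)) do.call(rbind, rows) else
      data.frame(fiber_id = integer(0), vertex_idx = integer(0),
                 x = numeric(0), y = numeric(0)),
      centerline_path, row.names = FALSE)
  }
  if (!is.null(metrics_path))
    utils::write.csv(as.data.frame(fibers), metrics_path, row.names = FALSE)
  invisible(list(centerlines = centerline_path, metrics = metrics_path))
}
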