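#' Parameters for the synthetic fiber-image generator
#'
#' Defaults describe a 256 x 256 px tile of a fiber-stained micrograph:
#' about 40 long, thin fibers (lognormal lengths around 80 px, 3 px wide)
#' with moderate orientation concentration, a 1 px optical blur and mild
#' sensor noise. Orientations are axial: doubled angles follow
#' von Mises(2 * mean_angle, kappa).
#'
#' @param image_size_px integer vector `(rows, cols)`.
#' @param n_fibers number of fibers to draw (>= 0).
#' @param mean_angle preferred orientation, radians in `[0, pi)`.
#' @param kappa von Mises concentration on doubled angles, >= 0 (`Inf` means
#'   all fibers exactly at `mean_angle`).
#' @param length_mu,length_sigma lognormal parameters of fiber length (px).
#' @param width_px fiber width (px), > 0.
#' @param fg_intensity,bg_intensity foreground/background intensity in `[0,1]`,
#'   with `bg_intensity < fg_intensity`.
#' @param blur_sigma_px Gaussian point-spread sigma applied after drawing, >= 0.
#' @param noise_sigma additive Gaussian noise sd, >= 0.
#' @param placement `"uniform"` scatters fibers freely (they may cross);
#'   `"nonoverlap"` rejects placements closer than one fiber width plus a
#'   2 px margin to any earlier fiber, and keeps fibers inside the frame.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a validated parameter list of class `fiber_sim_params`.
#' @export
fiber_sim_params <- function(image_size_px = c(256L, 256L),
                             n_fibers = 40L,
                             mean_angle = 0,
                             kappa = 2,
                             length_mu = log(80),
                             length_sigma = 0.25,
                             width_px = 3,
                             fg_intensity = 0.85,
                             bg_intensity = 0.10,
                             blur_sigma_px = 1,
                             noise_sigma = 0.02,
                             placement = c("uniform", "nonoverlap"),
                             seed = 1L) {
  placement <- match.arg(placement)
  if (length(image_size_px) != 2L || any(image_size_px < 1))
    stopf("`image_size_px` must be two positive integers")
  assert_scalar_num(n_fibers, "n_fibers", lower = 0)
  if (!identical(kappa, Inf)) assert_scalar_num(kappa, "kappa", lower = 0)
  assert_scalar_num(width_px, "width_px", lower = 1e-6)
  assert_scalar_num(bg_intensity, "bg_intensity", 0, 1)
  assert_scalar_num(fg_intensity, "fg_intensity", 0, 1)
  if (bg_intensity >= fg_intensity)
    stopf("require 0 <= bg_intensity < fg_intensity <= 1")
  assert_scalar_num(blur_sigma_px, "blur_sigma_px", lower = 0)
  assert_scalar_num(noise_sigma, "noise_sigma", lower = 0)
  assert_scalar_num(length_sigma, "length_sigma", lower = 0)
  structure(list(image_size_px = as.integer(image_size_px),
                 n_fibers = as.integer(n_fibers), mean_angle = wrap_axial(mean_angle),
                 kappa = kappa, length_mu = length_mu, length_sigma = length_sigma,
                 width_px = width_px, fg_intensity = fg_intensity,
                 bg_intensity = bg_intensity, blur_sigma_px = blur_sigma_px,
                 noise_sigma = noise_sigma, placement = placement,
                 seed = as.integer(seed)),
            class = "fiber_sim_params")
}

# Liang-Barsky clip of segment (p1, p2) to [0.5, xmax] x [0.5, ymax];
# returns NULL if fully outside.
clip_segment <- function(p1, p2, xmax, ymax) {
  d <- p2 - p1
  t0 <- 0; t1 <- 1
  for (i in 1:2) {
    lo <- 0.5; hi <- if (i == 1) xmax else ymax
    if (d[i] == 0) {
      if (p1[i] < lo || p1[i] > hi) return(NULL)
    } else {
      ta <- (lo - p1[i]) / d[i]; tb <- (hi - p1[i]) / d[i]
      if (ta > tb) { tmp <- ta; ta <- tb; tb <- tmp }
      t0 <- max(t0, ta); t1 <- min(t1, tb)
      if (t0 > t1) return(NULL)
    }
  }
  rbind(p1 + t0 * d, p1 + t1 * d)
}

# minimum distance between two 2-D segments (a1,a2) and (b1,b2)
segment_distance <- function(a1, a2, b1, b2) {
  pt_seg <- function(p, s1, s2) {
    d <- s2 - s1; L2 <- sum(d^2)
    t <- if (L2 == 0) 0 else max(0, min(1, sum((p - s1) * d) / L2))
    sqrt(sum((p - (s1 + t * d))^2))
  }
  seg_intersect <- function(p1, p2, p3, p4) {
    cr <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
    d1 <- cr(p3, p4, p1); d2 <- cr(p3, p4, p2); d3 <- cr(p1, p2, p3); d4 <- cr(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (seg_intersect(a1, a2, b1, b2)) return(0)
  min(pt_seg(a1, b1, b2), pt_seg(a2, b1, b2), pt_seg(b1, a1, a2), pt_seg(b2, a1, a2))
}

# anti-aliased rendering of one thick segment onto canvas (max-composited);
# coverage = clamp(width/2 + 0.5 - distance_to_segment, 0, 1)
draw_segment <- function(canvas, p1, p2, width) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  r <- width / 2 + 0.5
  cmin <- max(1L, floor(min(p1[1], p2[1]) - r)); cmax <- min(nc, ceiling(max(p1[1], p2[1]) + r))
  rmin <- max(1L, floor(min(p1[2], p2[2]) - r)); rmax <- min(nr, ceiling(max(p1[2], p2[2]) + r))
  if (cmin > cmax || rmin > rmax) return(canvas)
  xs <- cmin:cmax; ys <- rmin:rmax
  X <- matrix(xs, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  Y <- matrix(ys, nrow = length(ys), ncol = length(xs))
  d <- p2 - p1; L2 <- sum(d^2)
  if (L2 == 0) {
    dist <- sqrt((X - p1[1])^2 + (Y - p1[2])^2)
  } else {
    t <- ((X - p1[1]) * d[1] + (Y - p1[2]) * d[2]) / L2
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((X - (p1[1] + t * d[1]))^2 + (Y - (p1[2] + t * d[2]))^2)
  }
  cov <- pmin(pmax(width / 2 + 0.5 - dist, 0), 1)
  canvas[ys, xs] <- pmax(canvas[ys, xs], cov)
  canvas
}

#' Generate a synthetic fiber image with exact ground truth
#'
#' Draws `n_fibers` anti-aliased straight fibers whose axial angles are drawn
#' from the doubled-angle von Mises law, applies a Gaussian point-spread blur
#' and additive noise, and returns both the image and the ground truth
#' (sampled angles, drawn polylines, drawn arc lengths, and the true
#' doubled-angle mean vector length of the sampled angle set). Fibers crossing
#' the frame are clipped and the clipped geometry is what the ground truth
#' records.
#'
#' @param params a [fiber_sim_params()] list.
#' @return list with elements `image` (an [image2d()]) and `truth`, where
#'   `truth` has `angles`, `lengths`, `polylines` (list of 2 x 2 matrices of
#'   `(x, y)` endpoints), and `mvl_true`.
#' @export
gen_fiber_image <- function(params = fiber_sim_params()) {
  p <- params
  if (!inherits(p, "fiber_sim_params")) p <- do.call(fiber_sim_params, as.list(p))
  nr <- p$image_size_px[1]; nc <- p$image_size_px[2]
  with_seed(p$seed, {
    angles <- raxial_angles(p$n_fibers, p$mean_angle, p$kappa)
    lens <- stats::rlnorm(p$n_fibers, p$length_mu, p$length_sigma)
    canvas <- matrix(0, nr, nc)
    polys <- vector("list", p$n_fibers)
    kept_angles <- numeric(0); kept_lens <- numeric(0)
    placed <- list()
    for (i in seq_len(p$n_fibers)) {
      seg <- NULL
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (p$placement == "nonoverlap" && tries %% 500L == 0L) {
          # crowded configuration: redraw this fiber from the same laws
          angles[i] <- raxial_angles(1, p$mean_angle, p$kappa)
          lens[i] <- stats::rlnorm(1, p$length_mu, p$length_sigma)
        }
        if (p$placement == "nonoverlap") {
          # separation must clear the rendered support: half-widths plus the
          # blur halo on both sides, else neighboring fibers fuse after blur
          m <- p$width_px + 2 + 4 * p$blur_sigma_px
          half <- lens[i] / 2
          cx <- stats::runif(1, m + half * abs(cos(angles[i])) + 1,
                             nc - m - half * abs(cos(angles[i])))
          cy <- stats::runif(1, m + half * abs(sin(angles[i])) + 1,
                             nr - m - half * abs(sin(angles[i])))
        } else {
          cx <- stats::runif(1, 1, nc); cy <- stats::runif(1, 1, nr)
        }
        dvec <- c(cos(angles[i]), sin(angles[i])) * lens[i] / 2
        p1 <- c(cx, cy) - dvec; p2 <- c(cx, cy) + dvec
        cand <- clip_segment(p1, p2, nc, nr)
        if (is.null(cand)) { if (tries > 2000L) break else next }
        if (p$placement == "nonoverlap" && length(placed)) {
          mind <- min(vapply(placed, function(s)
            segment_distance(cand[1, ], cand[2, ], s[1, ], s[2, ]), numeric(1)))
          if (mind < p$width_px + 2 + 4 * p$blur_sigma_px) {
            if (tries > 2000L) break else next
          }
        }
        seg <- cand
        break
      }
      if (is.null(seg)) {
        if (p$placement == "nonoverlap")
          stopf("could not place %d non-overlapping fibers; reduce n_fibers or lengths", p$n_fibers)
        next
      }
      placed[[length(placed) + 1L]] <- seg
      polys[[length(placed)]] <- seg
      kept_angles <- c(kept_angles, angles[i])
      kept_lens <- c(kept_lens, sqrt(sum((seg[2, ] - seg[1, ])^2)))
      canvas <- draw_segment(canvas, seg[1, ], seg[2, ], p$width_px)
    }
    polys <- polys[seq_along(placed)]
    img <- p$bg_intensity + (p$fg_intensity - p$bg_intensity) * canvas
    if (p$blur_sigma_px > 0) img <- EBImage::gblur(img, sigma = p$blur_sigma_px)
    if (p$noise_sigma > 0) img <- img + stats::rnorm(length(img), 0, p$noise_sigma)
    img <- pmin(pmax(img, 0), 1)
    mvl_true <- if (length(kept_angles)) {
      sqrt(mean(cos(2 * kept_angles))^2 + mean(sin(2 * kept_angles))^2)
    } else NA_real_
    list(image = image2d(img),
         truth = list(angles = kept_angles, lengths = kept_lens,
                      polylines = polys, mvl_true = mvl_true))
  })
}

#' Write fiber ground truth to JSON
#'
#' @param truth the `truth` element returned by [gen_fiber_image()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fiber_truth <- function(truth, path) {
  jsonlite::write_json(list(
    angles = truth$angles, lengths = truth$lengths,
    mvl_true = truth$mvl_true,
    polylines = lapply(truth$polylines, function(m) unname(as.data.frame(m)))),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
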