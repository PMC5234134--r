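#' @name phantoms
#' @title Seeded jaw-like and hip-like CT phantoms with metal inserts
#'
#' @description
#' Parametric 2D Hounsfield-unit phantoms built from ellipse and arc
#' compositions, used as ground truth for metal-artifact-reduction
#' experiments. Each generator returns a \code{labeled_phantom}: a metal-free
#' truth image, the same image with metal inserts burned in at
#' \code{metal_hu}, a per-pixel tissue label map over
#' \{air, soft, bone, metal\}, the binary metal mask, and a set of 20 x 20
#' pixel regions of interest auto-placed in soft tissue and bone away from
#' the metal. Default tissue values: air -1000 HU, soft tissue 0-80 HU
#' (smooth seeded texture), bone 800-1500 HU, metal 3000 HU. Generation is
#' deterministic given \code{seed}.
#'
#' @param shape Image side in pixels (square grid, default 512; minimum 64).
#' @param fov_mm Physical side of the imaged field (default 200 mm).
#' @param metal_spec List of metal inserts, each
#'   \code{list(center = c(x_mm, y_mm), radius_mm = r, hu = 3000)}; x to the
#'   right and y upward from the isocenter. \code{NULL} uses the phantom's
#'   two default inserts; \code{list()} generates a metal-free phantom.
#' @param seed Integer seed controlling the tissue texture.
#' @param metal_hu CT value assigned to metal pixels (default 3000 HU).
#' @param metal_mu_mm Physical linear attenuation of the implant material in
#'   1/mm at the beam energy, used by the acquisition simulator. CT numbers
#'   clamp near 3000 HU (about 0.082/mm at 60 keV), but real implant alloys
#'   attenuate several times more, which is what starves the detector and
#'   creates severe streaks. Defaults: 1.0/mm (cobalt-chrome-like crown
#'   alloy) for the jaw phantom, 0.25/mm (titanium-like) for the hip
#'   phantom.
#'
#' @return A \code{labeled_phantom} list with elements \code{image_truth},
#'   \code{image_with_metal}, \code{tissue_labels} (integer matrix, levels
#'   in \code{attr(,"levels")}: air = 0, soft = 1, bone = 2, metal = 3),
#'   \code{metal_mask} (0/1 matrix), \code{rois} (list of [roi_spec()]),
#'   \code{pixel_spacing}, \code{fov_mm}, \code{kind}, and \code{seed}.
NULL

PHANTOM_LEVELS <- c(air = 0L, soft = 1L, bone = 2L, metal = 3L)

# mm coordinate grids of pixel centres (x right, y up, row down)
pixel_grid <- function(shape, fov_mm) {
  spacing <- fov_mm / shape
  x <- (seq_len(shape) - (shape + 1) / 2) * spacing
  y <- -x
  list(x = matrix(x, shape, shape, byrow = TRUE),
       y = matrix(y, shape, shape),
       spacing = spacing)
}

inside_ellipse <- function(g, cx, cy, a, b, theta = 0) {
  dx <- g$x - cx; dy <- g$y - cy
  xr <- dx * cos(theta) + dy * sin(theta)
  yr <- -dx * sin(theta) + dy * cos(theta)
  (xr / a)^2 + (yr / b)^2 <= 1
}

# annular arc band around centre (cx, cy): radius in [r_in, r_out] and
# polar angle (degrees, standard orientation) within [a0, a1]
inside_arc_band <- function(g, cx, cy, r_in, r_out, a0, a1) {
  dx <- g$x - cx; dy <- g$y - cy
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(dy, dx) * 180 / pi) %% 360
  r >= r_in & r <= r_out & ang >= a0 & ang <= a1
}

new_labeled_phantom <- function(truth, labels, spacing, fov_mm, kind, seed,
                                metal_hu, metal_mu_mm) {
  attr(labels, "levels") <- PHANTOM_LEVELS
  ph <- structure(list(
    image_truth = truth,
    image_with_metal = truth,
    tissue_labels = labels,
    metal_mask = matrix(0L, nrow(truth), ncol(truth)),
    rois = list(),
    pixel_spacing = spacing,
    fov_mm = fov_mm,
    kind = kind,
    seed = seed,
    metal_hu = metal_hu,
    metal_mu_mm = metal_mu_mm
  ), class = "labeled_phantom")
  ph
}

#' @export
print.labeled_phantom <- function(x, ...) {
  tab <- table(factor(x$tissue_labels, levels = PHANTOM_LEVELS,
                      labels = names(PHANTOM_LEVELS)))
  cat(sprintf("<labeled_phantom: %s, %dx%d px, %g mm FOV, seed %s>\n",
              x$kind, nrow(x$image_truth), ncol(x$image_truth), x$fov_mm,
              format(x$seed)))
  print(tab)
  invisible(x)
}

#' @rdname phantoms
#' @details
#' \code{make_jaw_phantom} emulates a mandible-level head section: an oval
#' soft-tissue head, a horseshoe bone arch carrying tooth-like ellipses, and
#' a vertebral body; the default metal inserts are two small dental fillings
#' (radius 1.8 mm) seated in two teeth.
#' @export
make_jaw_phantom <- function(shape = 512L, fov_mm = 200, metal_spec = NULL,
                             seed = 1L, metal_hu = 3000, metal_mu_mm = 1.0) {
  shape <- as.integer(shape)
  if (shape < 64L) stop("shape must be at least 64 pixels")
  g <- pixel_grid(shape, fov_mm)
  sc <- fov_mm / 200  # anatomy drawn for a 200 mm field, scaled with it
  truth <- matrix(-1000, shape, shape)
  labels <- matrix(PHANTOM_LEVELS[["air"]], shape, shape)

  head <- inside_ellipse(g, 0, 0, 72 * sc, 88 * sc)
  soft_tex <- 40 + 30 * smooth_noise_field(c(shape, shape), seed = seed)
  truth[head] <- pmin(pmax(soft_tex[head], 0), 80)
  labels[head] <- PHANTOM_LEVELS[["soft"]]

  bone_tex <- 1050 + 200 * smooth_noise_field(c(shape, shape), coarse = 12L,
                                              seed = seed + 1L)
  arch_c <- c(0, -12 * sc)
  arch <- inside_arc_band(g, arch_c[1], arch_c[2], 50 * sc, 64 * sc, 195, 345)
  vert <- inside_ellipse(g, 0, 52 * sc, 16 * sc, 11 * sc)
  bone <- (arch | vert) & head
  truth[bone] <- pmin(pmax(bone_tex[bone], 800), 1500)
  labels[bone] <- PHANTOM_LEVELS[["bone"]]

  tooth_angles <- seq(210, 330, by = 15)
  teeth <- matrix(FALSE, shape, shape)
  for (a in tooth_angles) {
    tc <- arch_c + 57 * sc * c(cos(a * pi / 180), sin(a * pi / 180))
    teeth <- teeth | inside_ellipse(g, tc[1], tc[2], 4.5 * sc, 6 * sc,
                                    theta = (a - 270) * pi / 180)
  }
  teeth <- teeth & head
  truth[teeth] <- 1500
  labels[teeth] <- PHANTOM_LEVELS[["bone"]]

  ph <- new_labeled_phantom(truth, labels, g$spacing, fov_mm, "jaw", seed,
                            metal_hu, metal_mu_mm)
  if (is.null(metal_spec)) {
    metal_spec <- lapply(c(240, 300), function(a) {
      ctr <- arch_c + 57 * sc * c(cos(a * pi / 180), sin(a * pi / 180))
      list(center = ctr, radius_mm = 2.5 * sc, hu = metal_hu)
    })
  }
  ph <- insert_metal(ph, metal_spec)
  ph$rois <- auto_place_rois(ph)
  ph
}

#' @rdname phantoms
#' @details
#' \code{make_hip_phantom} emulates a pelvis section: a wide body oval, a
#' pelvic bone ring, a sacrum, and two femoral heads; the default metal
#' inserts are two prosthesis heads (radius 6 mm), one in each femoral head.
#' @export
make_hip_phantom <- function(shape = 512L, fov_mm = 200, metal_spec = NULL,
                             seed = 1L, metal_hu = 3000, metal_mu_mm = 0.25) {
  shape <- as.integer(shape)
  if (shape < 64L) stop("shape must be at least 64 pixels")
  g <- pixel_grid(shape, fov_mm)
  sc <- fov_mm / 200
  truth <- matrix(-1000, shape, shape)
  labels <- matrix(PHANTOM_LEVELS[["air"]], shape, shape)

  body <- inside_ellipse(g, 0, 0, 95 * sc, 68 * sc)
  soft_tex <- 40 + 30 * smooth_noise_field(c(shape, shape), seed = seed)
  truth[body] <- pmin(pmax(soft_tex[body], 0), 80)
  labels[body] <- PHANTOM_LEVELS[["soft"]]

  bone_tex <- 1100 + 250 * smooth_noise_field(c(shape, shape), coarse = 12L,
                                              seed = seed + 1L)
  ring <- inside_ellipse(g, 0, 6 * sc, 52 * sc, 36 * sc) &
    !inside_ellipse(g, 0, 6 * sc, 38 * sc, 24 * sc)
  sacrum <- inside_ellipse(g, 0, 34 * sc, 15 * sc, 13 * sc)
  fem_l <- inside_ellipse(g, -64 * sc, -12 * sc, 19 * sc, 19 * sc)
  fem_r <- inside_ellipse(g, 64 * sc, -12 * sc, 19 * sc, 19 * sc)
  bone <- (ring | sacrum | fem_l | fem_r) & body
  truth[bone] <- pmin(pmax(bone_tex[bone], 800), 1500)
  labels[bone] <- PHANTOM_LEVELS[["bone"]]

  ph <- new_labeled_phantom(truth, labels, g$spacing, fov_mm, "hip", seed,
                            metal_hu, metal_mu_mm)
  if (is.null(metal_spec)) {
    metal_spec <- list(
      list(center = c(-64 * sc, -12 * sc), radius_mm = 9 * sc, hu = metal_hu),
      list(center = c(64 * sc, -12 * sc), radius_mm = 9 * sc, hu = metal_hu))
  }
  ph <- insert_metal(ph, metal_spec)
  ph$rois <- auto_place_rois(ph)
  ph
}

#' Insert metal discs into a phantom
#'
#' Burns circular metal inserts into \code{image_with_metal} and updates the
#' label map and metal mask; the metal-free truth image is unchanged. Every
#' insert must lie inside the anatomy (no air pixels under the disc) and must
#' not overlap previously inserted metal.
#'
#' @param phantom A \code{labeled_phantom}.
#' @param spec List of inserts as in [make_jaw_phantom()]; an empty list is
#'   the identity.
#' @return The updated \code{labeled_phantom}.
#' @export
insert_metal <- function(phantom, spec) {
  stopifnot(inherits(phantom, "labeled_phantom"))
  if (length(spec) == 0) return(phantom)
  g <- pixel_grid(nrow(phantom$image_truth), phantom$fov_mm)
  for (s in spec) {
    hu <- if (is.null(s$hu)) phantom$metal_hu else s$hu
    disc <- (g$x - s$center[1])^2 + (g$y - s$center[2])^2 <= s$radius_mm^2
    if (!any(disc))
      stop("metal insert smaller than one pixel or outside the grid")
    if (any(phantom$tissue_labels[disc] == PHANTOM_LEVELS[["air"]]))
      stop("metal insert extends outside the anatomy")
    if (any(phantom$metal_mask[disc] == 1L))
      stop("metal insert overlaps existing metal")
    phantom$image_with_metal[disc] <- hu
    phantom$tissue_labels[disc] <- PHANTOM_LEVELS[["metal"]]
    phantom$metal_mask[disc] <- 1L
  }
  phantom
}

#' Region-of-interest specification
#'
#' A rectangular pixel block used for mean/standard-deviation reporting.
#' Indices are 1-based and inclusive, rows increasing downward.
#'
#' @param row,col Top-left pixel of the block.
#' @param height,width Block size in pixels (default 20 x 20).
#' @param label Optional tissue-class tag.
#' @return An object of class \code{roi_spec}.
#' @export
roi_spec <- function(row, col, height = 20L, width = 20L, label = NA_character_) {
  stopifnot(row >= 1, col >= 1, height >= 1, width >= 1)
  structure(list(row = as.integer(row), col = as.integer(col),
                 height = as.integer(height), width = as.integer(width),
                 label = label), class = "roi_spec")
}

# Deterministically place up to n 20x20 ROIs per tissue class (soft, bone),
# requiring class purity and a clearance margin from any metal pixel.
auto_place_rois <- function(phantom, size = 20L, n_per_class = 4L,
                            metal_clearance = 12L) {
  labels <- phantom$tissue_labels
  n <- nrow(labels)
  metal <- phantom$metal_mask == 1L
  # distance-to-metal proxy: dilate the metal mask by the clearance box
  near_metal <- metal
  if (any(metal)) {
    idx <- which(metal, arr.ind = TRUE)
    r0 <- pmax(idx[, 1] - metal_clearance, 1L)
    r1 <- pmin(idx[, 1] + metal_clearance, n)
    c0 <- pmax(idx[, 2] - metal_clearance, 1L)
    c1 <- pmin(idx[, 2] + metal_clearance, n)
    for (k in seq_len(nrow(idx)))
      near_metal[r0[k]:r1[k], c0[k]:c1[k]] <- TRUE
  }
  rois <- list()
  stride <- max(4L, size %/% 2L)
  starts <- seq(1L, n - size + 1L, by = stride)
  for (cls in c("soft", "bone")) {
    lev <- PHANTOM_LEVELS[[cls]]
    cand <- list()
    for (r in starts) for (c in starts) {
      blk_lab <- labels[r:(r + size - 1L), c:(c + size - 1L)]
      if (all(blk_lab == lev) &&
          !any(near_metal[r:(r + size - 1L), c:(c + size - 1L)]))
        cand[[length(cand) + 1L]] <- c(r, c)
    }
    if (length(cand) == 0) next
    pick <- unique(round(seq(1, length(cand), length.out = min(n_per_class,
                                                               length(cand)))))
    for (p in pick)
      rois[[length(rois) + 1L]] <- roi_spec(cand[[p]][1], cand[[p]][2],
                                            size, size, label = cls)
  }
  rois
}
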