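# Synthetic mandible-like template mesh.
#
# The template is a closed swept tube: a midline-symmetric path runs from the
# top of the right condyle, down the right ramus, around the gonial bend and
# the horseshoe body through the chin, and back up to the left condyle.
# Elliptical cross-sections (broad axis E1, thin axis E2) are swept along the
# path and the two ends are closed with rounded caps, giving a watertight
# genus-0 surface. Condyle knobs come from inflating the section near the
# ends; the coronoid processes and the genial tubercle are smooth Gaussian
# displacement bumps added afterwards. Frame convention: +x anterior,
# +y subject-left, +z superior, origin at the centroid.
#
# Geometry is chosen so that the automatic landmark rules are well-posed:
# the posterior ramus border is a straight vertical ridge (stable posterior
# support plane), the inferior body border is planar over the mid-body
# (stable inferior support plane), and the gonial bend between them is a
# rounded corner their bisecting plane crosses.

mandible_shape_defaults <- function() {
  list(
    # path control points for the right half (u in [0, 0.5]); mirrored for the left
    path_u = c(0.000, 0.045, 0.105, 0.175, 0.250, 0.315, 0.375, 0.430, 0.470, 0.500),
    path_x = c(-30.5, -30.5, -30.5, -30.5, -30.0, -26.0, -17.0,  -5.0,   9.0,  27.0),
    path_y = c(-30.5, -29.5, -28.0, -27.0, -26.0, -25.0, -24.0, -21.0, -15.5,   0.0),
    path_z = c( 15.0,   9.0,   1.0,  -5.0, -11.0, -14.5, -16.0, -16.0, -16.0, -16.0),
    # section semi-axes (mm) at the same u stations: a along E1 (broad), b along E2 (thin)
    a      = c(  5.0,   7.5,  11.0,  11.0,  11.0,   9.5,   7.0,   7.0,   7.0,   7.0),
    b      = c(  7.5,   3.6,   3.5,   3.5,   3.6,   4.2,   5.0,   5.0,   5.0,   5.0),
    cap_height = 4.5,           # mm, rounded end caps above the condyles
    coronoid_center = c(-19.0, 25.0, 9.0),   # |y| used; mirrored pair
    coronoid_height = 12.0,     # mm displacement at bump center
    coronoid_sigma = 3.2,       # mm Gaussian width
    coronoid_dir = c(0.25, 0.0, 1.0),        # up and slightly forward
    gt_center = c(-100, 0, -14),             # placeholder; set from chin below
    gt_height = 6.0,
    gt_sigma = 2.2
  )
}

blend_hint <- function(u) {
  # section "up hint": +x near the rami (vertical path), +z along the body
  w_ram <- logistic((0.30 - u) / 0.04) + logistic((u - 0.70) / 0.04)
  w_ram <- pmin(w_ram, 1)
  ax <- w_ram
  az <- 1 - w_ram
  cbind(ax, 0, az) / sqrt(ax^2 + az^2)
}

#' Generate the synthetic mandible template mesh
#'
#' Builds the canonical-frame, bilaterally symmetric, watertight
#' mandible-like triangle mesh described above, at roughly the size of a
#' one-month-old miniature pig mandible. Anchor positions for the manually
#' identified landmarks (AMF, MMF, PMF, NO) are attached as the
#' `"manual_anchors"` attribute (snapped to mesh vertices).
#'
#' @param shape Shape parameter list; see `mandible_shape_defaults()`.
#' @param resolution Approximate target vertex count (default 1800,
#'   minimum 500).
#' @return A watertight [triangle_mesh()] centred on its centroid, with
#'   attributes `manual_anchors` (data frame code/side/x/y/z) and
#'   `resolution` used.
#' @export
generate_template_mesh <- function(shape = mandible_shape_defaults(),
                                   resolution = 1800) {
  if (resolution < 500)
    stop("resolution below 500 vertices cannot represent the mandible features")
  # ring/segment counts from the vertex budget (rings ~ 1.4 * segments)
  n_seg <- max(20L, 2L * round(sqrt(resolution / 1.6) / 2))   # even
  n_ring <- max(29L, round(1.4 * n_seg))
  if (n_ring %% 2L == 0L) n_ring <- n_ring + 1L               # odd: station at u = 0.5
  # symmetric full-path control points
  pu <- c(shape$path_u, 1 - rev(shape$path_u[-length(shape$path_u)]))
  px <- c(shape$path_x, rev(shape$path_x[-length(shape$path_x)]))
  py <- c(shape$path_y, -rev(shape$path_y[-length(shape$path_y)]))
  pz <- c(shape$path_z, rev(shape$path_z[-length(shape$path_z)]))
  au <- c(shape$a, rev(shape$a[-length(shape$a)]))
  bu <- c(shape$b, rev(shape$b[-length(shape$b)]))
  fx <- stats::splinefun(pu, px, method = "natural")
  fy <- stats::splinefun(pu, py, method = "natural")
  fz <- stats::splinefun(pu, pz, method = "natural")
  fa <- stats::splinefun(pu, au, method = "natural")
  fb <- stats::splinefun(pu, bu, method = "natural")
  # station parameters equally spaced in arc length (the path speed varies
  # several-fold between ramus and chin); symmetrized so station i mirrors
  # station n_ring + 1 - i exactly
  ud <- seq(0, 1, length.out = 2001)
  Pd <- cbind(fx(ud), fy(ud), fz(ud))
  seg <- sqrt(rowSums((Pd[-1, ] - Pd[-nrow(Pd), ])^2))
  arc <- c(0, cumsum(seg))
  uu <- stats::approx(arc, ud, xout = seq(0, arc[length(arc)],
                                          length.out = n_ring))$y
  uu <- (uu + rev(1 - uu)) / 2
  P <- cbind(fx(uu), fy(uu), fz(uu))
  Tn <- cbind(fx(uu, deriv = 1), fy(uu, deriv = 1), fz(uu, deriv = 1))
  Tn <- Tn / sqrt(rowSums(Tn^2))
  A <- blend_hint(uu)
  E2 <- cross3_rows(Tn, A)
  e2n <- sqrt(rowSums(E2^2))
  if (any(e2n < 1e-6)) stop("degenerate sweep frame (tangent parallel to hint)")
  E2 <- E2 / e2n
  E1 <- cross3_rows(E2, Tn)
  E1 <- E1 / sqrt(rowSums(E1^2))
  aa <- fa(uu); bb <- fb(uu)
  theta <- 2 * pi * (seq_len(n_seg) - 1L) / n_seg
  ct <- cos(theta); st <- sin(theta)
  # rounded caps: shrink rings beyond the path ends, then an apex vertex.
  # Start cap rings run pole-to-equator so they chain into the main rings.
  cap_phis <- c(0.75, 0.5, 0.25) * (pi / 2)   # phi = 0 equator, pi/2 pole
  start_cap <- lapply(cap_phis, function(phi)
    ring_at_cap(P[1, ], -Tn[1, ], E1[1, ], E2[1, ], aa[1], bb[1],
                shape$cap_height, phi, ct, st))
  main_rings <- lapply(seq_len(n_ring), function(i)
    t(P[i, ] + t(outer(ct, E1[i, ]) * aa[i] + outer(st, E2[i, ]) * bb[i])))
  end_cap <- lapply(rev(cap_phis), function(phi)
    ring_at_cap(P[n_ring, ], Tn[n_ring, ], E1[n_ring, ], E2[n_ring, ],
                aa[n_ring], bb[n_ring], shape$cap_height, phi, ct, st))
  all_rings <- c(start_cap, main_rings, end_cap)
  nr <- length(all_rings)
  verts <- do.call(rbind, all_rings)
  apex_start <- P[1, ] - Tn[1, ] * shape$cap_height
  apex_end <- P[n_ring, ] + Tn[n_ring, ] * shape$cap_height
  verts <- rbind(verts, apex_start, apex_end)
  i_apex_start <- nrow(verts) - 1L
  i_apex_end <- nrow(verts)
  ring_idx <- function(r) (r - 1L) * n_seg + seq_len(n_seg)
  faces <- vector("list", nr + 1L)
  for (r in seq_len(nr - 1L)) {
    i1 <- ring_idx(r); i2 <- ring_idx(r + 1L)
    j <- seq_len(n_seg); jn <- c(seq_len(n_seg)[-1], 1L)
    faces[[r]] <- rbind(cbind(i1[j], i2[j], i2[jn]),
                        cbind(i1[j], i2[jn], i1[jn]))
  }
  first <- ring_idx(1L); last <- ring_idx(nr)
  j <- seq_len(n_seg); jn <- c(seq_len(n_seg)[-1], 1L)
  faces[[nr]] <- cbind(first[jn], first[j], rep(i_apex_start, n_seg))
  faces[[nr + 1L]] <- cbind(last[j], last[jn], rep(i_apex_end, n_seg))
  faces <- do.call(rbind, faces)
  mesh <- triangle_mesh(verts, faces, validate = FALSE)
  mesh <- orient_mesh(mesh)

  # coronoid processes: smooth displacement bumps on the anterior ramus tops.
  # Bump centres snap to actual surface vertices so the displaced apex is a
  # single unambiguous vertex (stable curvature argmax under deformation).
  snap <- function(target) {
    i <- which.min(rowSums(sweep(mesh$vertices, 2, target)^2))
    mesh$vertices[i, ]
  }
  cc <- shape$coronoid_center
  for (s in c(1, -1)) {
    ctr <- snap(c(cc[1], s * abs(cc[2]), cc[3]))
    dir <- unit_vector(c(shape$coronoid_dir[1], s * shape$coronoid_dir[2], shape$coronoid_dir[3]))
    w <- exp(-rowSums(sweep(mesh$vertices, 2, ctr)^2) / shape$coronoid_sigma^2)
    mesh$vertices <- mesh$vertices + shape$coronoid_height * w %o% dir
  }
  # genial tubercle: posterior-pointing bump on the lingual chin midline;
  # centre snapped to an exact midline vertex so the tip stays sagittal
  chin_inner_x <- fx(0.5) - fb(0.5)   # inner (lingual) chin wall
  mid_idx <- which(abs(mesh$vertices[, 2]) < 1e-9)
  gt_target <- c(chin_inner_x, 0, fz(0.5) + 2)
  gt_ctr <- mesh$vertices[mid_idx[which.min(
    rowSums(sweep(mesh$vertices[mid_idx, , drop = FALSE], 2, gt_target)^2))], ]
  w <- exp(-rowSums(sweep(mesh$vertices, 2, gt_ctr)^2) / shape$gt_sigma^2)
  mesh$vertices <- mesh$vertices + shape$gt_height * w %o% c(-1, 0, 0)

  # exact bilateral symmetrization (averages away spline/cap float noise)
  mesh$vertices <- symmetrize_tube(mesh$vertices, nr, n_seg, i_apex_start, i_apex_end)
  # canonical frame: origin at centroid
  ctr <- colMeans(mesh$vertices)
  mesh$vertices <- sweep(mesh$vertices, 2, ctr)

  anchors <- manual_anchor_table(mesh, ctr)
  attr(mesh, "manual_anchors") <- anchors
  attr(mesh, "resolution") <- nrow(mesh$vertices)
  mesh
}

ring_at_cap <- function(ctr, out_dir, E1, E2, a, b, cap_h, phi, ct, st) {
  # phi: 0 at equator, pi/2 at pole
  scale <- cos(phi)
  off <- cap_h * sin(phi)
  t(ctr + off * out_dir + t(outer(ct, E1) * (a * scale) + outer(st, E2) * (b * scale)))
}

symmetrize_tube <- function(v, nr, n_seg, i_apex_start, i_apex_end) {
  # ring r pairs with ring nr+1-r at the same theta index; y flips
  for (r in seq_len(floor(nr / 2))) {
    i1 <- (r - 1L) * n_seg + seq_len(n_seg)
    i2 <- (nr - r) * n_seg + seq_len(n_seg)
    m1 <- v[i1, , drop = FALSE]
    m2 <- v[i2, , drop = FALSE]
    avg_x <- (m1[, 1] + m2[, 1]) / 2
    avg_y <- (m1[, 2] - m2[, 2]) / 2
    avg_z <- (m1[, 3] + m2[, 3]) / 2
    v[i1, ] <- cbind(avg_x, avg_y, avg_z)
    v[i2, ] <- cbind(avg_x, -avg_y, avg_z)
  }
  if (nr %% 2L == 1L) {
    # the midline ring lies in the sagittal plane (every vertex is its own
    # mirror image at the same theta): just zero the residual y component
    r <- (nr + 1L) / 2
    i1 <- (r - 1L) * n_seg + seq_len(n_seg)
    v[i1, 2] <- 0
  }
  a1 <- v[i_apex_start, ]; a2 <- v[i_apex_end, ]
  v[i_apex_start, ] <- c((a1[1] + a2[1]) / 2, (a1[2] - a2[2]) / 2, (a1[3] + a2[3]) / 2)
  v[i_apex_end, ] <- v[i_apex_start, ] * c(1, -1, 1)
  v
}

manual_anchor_table <- function(mesh, pre_center) {
  # anatomical anchor targets in construction coordinates, then recentred
  targets <- rbind(
    AMF_L = c(24,  8, -17), AMF_R = c(24, -8, -17),
    MMF_L = c(17, 14, -17), MMF_R = c(17, -14, -17),
    PMF_L = c(7, 19, -17),  PMF_R = c(7, -19, -17),
    NO_L = c(-8, 22.5, -21), NO_R = c(-8, -22.5, -21)
  )
  targets <- sweep(targets, 2, pre_center)
  out <- lapply(rownames(targets), function(nm) {
    d2 <- rowSums(sweep(mesh$vertices, 2, targets[nm, ])^2)
    i <- which.min(d2)
    parts <- strsplit(nm, "_")[[1]]
    data.frame(code = parts[1], side = parts[2],
               x_mm = mesh$vertices[i, 1], y_mm = mesh$vertices[i, 2],
               z_mm = mesh$vertices[i, 3], vertex = i)
  })
  df <- do.call(rbind, out)
  # exact bilateral symmetry of anchors: mirror the left picks onto the right
  for (code in unique(df$code)) {
    iL <- which(df$code == code & df$side == "L")
    iR <- which(df$code == code & df$side == "R")
    df[iR, c("x_mm", "y_mm", "z_mm")] <-
      df[iL, c("x_mm", "y_mm", "z_mm")] * rep(c(1, -1, 1), each = 1)
    df$vertex[iR] <- NA_integer_
  }
  # re-snap mirrored anchors to actual vertices (mesh is symmetric, so exact)
  for (i in which(is.na(df$vertex))) {
    d2 <- rowSums(sweep(mesh$vertices, 2, as.numeric(df[i, c("x_mm", "y_mm", "z_mm")]))^2)
    j <- which.min(d2)
    df$vertex[i] <- j
    df[i, c("x_mm", "y_mm", "z_mm")] <- mesh$vertices[j, ]
  }
  rownames(df) <- NULL
  df
}
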