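# trilinear interpolation of a 3D volume at arbitrary mm coordinates;
# voxel centres sit at (i - 0.5) * voxel_size
interp3 <- function(vol, coords_mm, voxel_size) {
  d <- dim(vol)
  u <- sweep(coords_mm, 2, voxel_size, "/") + 0.5
  for (ax in 1:3) u[, ax] <- pmin(pmax(u[, ax], 1), d[ax])
  i0 <- pmin(floor(u), matrix(rep(d - 1, each = nrow(u)), ncol = 3))
  f <- u - i0
  g <- function(ix, iy, iz) {
    vol[cbind(ix, iy, iz)]
  }
  x0 <- i0[, 1]; y0 <- i0[, 2]; z0 <- i0[, 3]
  fx <- f[, 1]; fy <- f[, 2]; fz <- f[, 3]
  c00 <- g(x0, y0, z0) * (1 - fx) + g(x0 + 1, y0, z0) * fx
  c10 <- g(x0, y0 + 1, z0) * (1 - fx) + g(x0 + 1, y0 + 1, z0) * fx
  c01 <- g(x0, y0, z0 + 1) * (1 - fx) + g(x0 + 1, y0, z0 + 1) * fx
  c11 <- g(x0, y0 + 1, z0 + 1) * (1 - fx) + g(x0 + 1, y0 + 1, z0 + 1) * fx
  c0 <- c00 * (1 - fy) + c10 * fy
  c1 <- c01 * (1 - fy) + c11 * fy
  c0 * (1 - fz) + c1 * fz
}

#' Three-class tissue segmentation by Gaussian mixture
#'
#' Fits a three-component univariate Gaussian mixture to the masked
#' intensities (via mclust) and takes the posterior class probabilities as
#' partial volume estimates. Classes are identified by ascending mean
#' intensity, the T1-like ordering CSF < GM < WM. Images whose masked
#' intensities take three or fewer distinct values are noiseless label maps:
#' they are assigned exactly by nearest level (a zero-variance mixture is
#' outside the model space).
#'
#' @param volume 3D intensity array.
#' @param mask Logical brain mask.
#' @return List of class `tissue_segmentation`: partial-volume arrays `csf`,
#'   `gm`, `wm` (zero outside the mask), the `mask`, and the fitted class
#'   `means`.
#' @importFrom mclust Mclust mclustBIC
#' @export
segment_tissues <- function(volume, mask) {
  if (!any(mask)) stop("empty mask")
  x <- volume[mask]
  ux <- unique(round(x, 8))
  if (length(ux) < 3) stop("fewer than three intensity modes inside the mask")
  if (length(ux) == 3) {
    lev <- sort(ux)
    post <- outer(round(x, 8), lev, function(a, b) as.numeric(a == b))
    means <- lev
  } else {
    # deterministic, intensity-spanning subset for initialization; full
    # hierarchical initialization is quadratic in the voxel count
    sub <- order(x)[unique(round(seq(1, length(x), length.out = 2000)))]
    fit <- tryCatch(
      mclust::Mclust(x, G = 3, modelNames = "V", verbose = FALSE,
                     initialization = list(subset = sub)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      fit <- mclust::Mclust(x, G = 3, modelNames = "E", verbose = FALSE,
                            initialization = list(subset = sub))
    }
    ord <- order(fit$parameters$mean)
    post <- fit$z[, ord, drop = FALSE]
    means <- fit$parameters$mean[ord]
  }
  mk <- function(j) {
    a <- array(0, dim(volume))
    a[mask] <- post[, j]
    a
  }
  structure(
    list(csf = mk(1), gm = mk(2), wm = mk(3), mask = mask, means = means),
    class = "tissue_segmentation"
  )
}

#' Tissue volumes from a segmentation
#'
#' Partial volume estimates summed over the mask and scaled by the voxel
#' volume, reported in mL.
#'
#' @param seg A [segment_tissues()] result.
#' @param voxel_volume_mm3 Voxel volume in cubic mm.
#' @return One-row tibble: `csf_ml`, `gm_ml`, `wm_ml`.
#' @export
tissue_volumes <- function(seg, voxel_volume_mm3) {
  stopifnot(inherits(seg, "tissue_segmentation"))
  tibble::tibble(
    csf_ml = sum(seg$csf) * voxel_volume_mm3 / 1000,
    gm_ml = sum(seg$gm) * voxel_volume_mm3 / 1000,
    wm_ml = sum(seg$wm) * voxel_volume_mm3 / 1000
  )
}

# boundary voxels of a mask: in-mask voxels with a 6-neighbour outside
mask_boundary <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  inner <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  all_nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  inner & !all_nb
}

#' Perpendicular edge displacement between two aligned volumes
#'
#' The two-time-point volumetry core: at every brain/nonbrain edge point of
#' the first time point, an intensity profile is sampled along the outward
#' surface normal in both volumes and the displacement of the brain edge is
#' estimated as the sub-voxel translation that best aligns the follow-up
#' profile with the baseline profile (least-squares over a shift grid with
#' parabolic refinement). Matching the whole profile rather than a single
#' intensity level keeps the estimate unbiased when the outermost tissue
#' shell is thin relative to the voxel size. Displacement is in mm along the
#' normal, positive for outward growth.
#'
#' Edge points come from the boundary of the baseline brain mask; normals
#' are the gradient of a Gaussian-smoothed mask indicator. Each point also
#' carries the surface area it represents: the voxel face area divided by
#' the largest normal component, the projected-area estimate of the surface
#' patch crossing that voxel. Volumes must already be rigidly aligned
#' (identity for phantoms; a registration hook belongs upstream). Points
#' whose best match hits the edge of the search range are dropped and
#' counted.
#'
#' @param vol_pre,vol_post 3D intensity arrays on a common grid.
#' @param brain_mask Baseline brain mask (logical array).
#' @param voxel_size Voxel size per axis, mm.
#' @param profile_halfwidth_mm Half-length of the sampled profile, mm.
#' @param step_mm Profile sampling step, mm.
#' @param max_shift_mm Largest displacement searched, mm.
#' @param presmooth_sigma_vox Gaussian pre-smoothing (voxels) applied
#'   identically to both volumes before sampling. A common smoothing leaves
#'   edge displacements unchanged but makes the sub-voxel match insensitive
#'   to the interpolation grid phase.
#' @return List of class `edge_point_set`: `points` tibble (voxel indices,
#'   unit normals, `area_mm2`, `displacement_mm`), `n_dropped`,
#'   `voxel_size`.
#' @export
edge_displacement <- function(vol_pre, vol_post, brain_mask, voxel_size,
                              profile_halfwidth_mm = NULL, step_mm = NULL,
                              max_shift_mm = NULL, presmooth_sigma_vox = 1) {
  stopifnot(all(dim(vol_pre) == dim(vol_post)),
            all(dim(vol_pre) == dim(brain_mask)))
  d <- dim(vol_pre)
  if (is.null(profile_halfwidth_mm)) profile_halfwidth_mm <- 2 * max(voxel_size)
  if (is.null(step_mm)) step_mm <- min(voxel_size) / 4
  if (is.null(max_shift_mm)) max_shift_mm <- max(voxel_size)
  if (presmooth_sigma_vox > 0) {
    kpx <- gaussian_conv_matrix(d[1], presmooth_sigma_vox)
    kpy <- gaussian_conv_matrix(d[2], presmooth_sigma_vox)
    kpz <- gaussian_conv_matrix(d[3], presmooth_sigma_vox)
    vol_pre <- conv3_separable(vol_pre, kpx, kpy, kpz)
    vol_post <- conv3_separable(vol_post, kpx, kpy, kpz)
  }

  bnd <- which(mask_boundary(brain_mask))
  if (length(bnd) == 0) stop("mask has no boundary")
  ijk <- arrayInd(bnd, d)
  centre_mm <- sweep(ijk - 0.5, 2, voxel_size, "*")

  # outward normals from the smoothed mask indicator gradient
  sig <- 2.5
  kx <- gaussian_conv_matrix(d[1], sig)
  ky <- gaussian_conv_matrix(d[2], sig)
  kz <- gaussian_conv_matrix(d[3], sig)
  sm <- conv3_separable(brain_mask + 0, kx, ky, kz)
  grad_axis <- function(ax) {
    shift_p <- ijk
    shift_m <- ijk
    shift_p[, ax] <- pmin(ijk[, ax] + 1, d[ax])
    shift_m[, ax] <- pmax(ijk[, ax] - 1, 1)
    (sm[shift_p] - sm[shift_m]) / ((shift_p[, ax] - shift_m[, ax]) * voxel_size[ax])
  }
  gr <- cbind(grad_axis(1), grad_axis(2), grad_axis(3))
  nrm <- sqrt(rowSums(gr^2))
  ok <- nrm > 1e-9
  normals <- -gr[ok, , drop = FALSE] / nrm[ok]  # mask decreases outward
  centre_mm <- centre_mm[ok, , drop = FALSE]
  ijk <- ijk[ok, , drop = FALSE]
  n_pt <- nrow(normals)

  offs <- seq(-profile_halfwidth_mm, profile_halfwidth_mm, by = 3 * step_mm)
  shifts <- seq(-max_shift_mm, max_shift_mm, by = step_mm)
  p_post <- vapply(offs, function(o) {
    interp3(vol_post, centre_mm + o * normals, voxel_size)
  }, numeric(n_pt))
  ssd <- matrix(0, n_pt, length(shifts))
  for (si in seq_along(shifts)) {
    p_pre_s <- vapply(offs, function(o) {
      interp3(vol_pre, centre_mm + (o + shifts[si]) * normals, voxel_size)
    }, numeric(n_pt))
    ssd[, si] <- rowSums((p_post - p_pre_s)^2)
  }
  best <- max.col(-ssd, ties.method = "first")
  # vol_post(o) ~ vol_pre(o + s): the edge moved by -s along the normal
  disp <- -shifts[best]
  inner <- best > 1 & best < length(shifts)
  i0 <- best[inner]
  ri <- which(inner)
  y0 <- ssd[cbind(ri, i0)]
  ym <- ssd[cbind(ri, i0 - 1)]
  yp <- ssd[cbind(ri, i0 + 1)]
  den <- ym - 2 * y0 + yp
  # an exact match at the grid minimum needs no refinement; a lopsided
  # parabola through it would fabricate a sub-step shift
  exact <- y0 <= 1e-12 * pmax(ym, yp)
  adj <- ifelse(den > 0 & !exact, 0.5 * (ym - yp) / den * step_mm, 0)
  disp[inner] <- disp[inner] - adj
  keep <- inner

  area <- prod(sort(voxel_size)[1:2]) / apply(abs(normals), 1, max)
  structure(
    list(
      points = tibble::tibble(
        i = ijk[keep, 1], j = ijk[keep, 2], k = ijk[keep, 3],
        nx = normals[keep, 1], ny = normals[keep, 2], nz = normals[keep, 3],
        area_mm2 = area[keep],
        displacement_mm = disp[keep]
      ),
      n_dropped = sum(!keep),
      voxel_size = voxel_size
    ),
    class = "edge_point_set"
  )
}

#' Percent brain volume change from edge displacements
#'
#' Each edge point's perpendicular displacement, weighted by the surface
#' area its voxel represents, contributes to the global volume change:
#' `PBVC = 100 * sum(area_i * displacement_i) / brain_volume`, which equals
#' the area-weighted mean displacement times the total surface area over the
#' brain volume.
#'
#' @param edges An [edge_displacement()] result.
#' @param brain_volume_mm3 Baseline brain volume, cubic mm (e.g. mask voxel
#'   count times voxel volume).
#' @param min_points Guard against meaningless estimates from few edges.
#' @return One-row tibble of class `volume_change_result`: `pbvc`,
#'   `mean_displacement_mm` (area-weighted), `n_edge_points`,
#'   `surface_area_mm2`.
#' @export
pbvc <- function(edges, brain_volume_mm3, min_points = 100) {
  stopifnot(inherits(edges, "edge_point_set"))
  n <- nrow(edges$points)
  if (n < min_points) stop("too few edge points for a volume change estimate")
  a <- edges$points$area_mm2
  dsp <- edges$points$displacement_mm
  sa <- sum(a)
  md <- sum(a * dsp) / sa
  out <- tibble::tibble(
    pbvc = 100 * md * sa / brain_volume_mm3,
    mean_displacement_mm = md,
    n_edge_points = n,
    surface_area_mm2 = sa
  )
  class(out) <- c("volume_change_result", class(out))
  out
}

#' Count lesions as 26-connected components
#'
#' Components of a binary mask under 26-connectivity (face, edge or corner
#' adjacency), keeping those at least `min_size_mm3` large.
#'
#' @param mask Logical 3D array.
#' @param voxel_size Voxel size per axis, mm.
#' @param min_size_mm3 Minimum lesion volume retained.
#' @return One-row tibble: `n_lesions` and a list-column `sizes_mm3`.
#' @export
count_lesions <- function(mask, voxel_size = c(1, 1, 1), min_size_mm3 = 5) {
  d <- dim(mask)
  vox_vol <- prod(voxel_size)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(tibble::tibble(n_lesions = 0L, sizes_mm3 = list(numeric(0))))
  }
  comp <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  cur <- 0L
  sizes <- integer(0)
  for (start in idx) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    comp[start] <- cur
    queue <- start
    n_vox <- 1L
    while (length(queue) > 0) {
      v <- queue[[1]]
      queue <- queue[-1]
      p <- arrayInd(v, d)
      cand <- sweep(nb, 2, as.vector(p), "+")
      ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
        cand[, 2] >= 1 & cand[, 2] <= d[2] &
        cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[ok, , drop = FALSE]
      lin <- (cand[, 3] - 1) * d[1] * d[2] + (cand[, 2] - 1) * d[1] + cand[, 1]
      new <- lin[mask[lin] & comp[lin] == 0L]
      if (length(new)) {
        comp[new] <- cur
        queue <- c(queue, new)
        n_vox <- n_vox + length(new)
      }
    }
    sizes <- c(sizes, n_vox)
  }
  sizes_mm3 <- sizes * vox_vol
  keep <- sizes_mm3 >= min_size_mm3
  tibble::tibble(
    n_lesions = sum(keep),
    sizes_mm3 = list(sort(sizes_mm3[keep], decreasing = TRUE))
  )
}

#' Percent volume change between two tissue volumes
#'
#' Same arithmetic as [percent_change()], named for the volumetric report.
#'
#' @param pre_ml,post_ml Volumes in mL; `pre_ml` must be positive.
#' @return Percent change.
#' @examples
#' percent_volume_change(733, 718)  # -2.05
#' @export
percent_volume_change <- function(pre_ml, post_ml) {
  if (any(pre_ml <= 0)) stop("pre volume must be positive")
  percent_change(pre_ml, post_ml)
}

#' Two-time-point structural analysis of a volume pair
#'
#' Convenience wrapper running segmentation, tissue volumes, edge
#' displacement and PBVC for a registered pair of T1-like volumes.
#'
#' @param vol_pre,vol_post Aligned 3D intensity arrays.
#' @param brain_mask Baseline brain mask.
#' @param voxel_size Voxel size per axis, mm.
#' @param register Rigid-registration hook `(vol_post, vol_pre) -> vol_post`;
#'   identity by default (phantoms share a grid).
#' @return List: `volumes` tibble (per session tissue mL and percent change),
#'   `pbvc` ([pbvc()] row), `edges`, and the two segmentations.
#' @export
analyze_volume_pair <- function(vol_pre, vol_post, brain_mask, voxel_size,
                                register = function(post, pre) post) {
  vol_post <- register(vol_post, vol_pre)
  vox_vol <- prod(voxel_size)
  seg_pre <- segment_tissues(vol_pre, brain_mask)
  seg_post <- segment_tissues(vol_post, brain_mask)
  tv_pre <- tissue_volumes(seg_pre, vox_vol)
  tv_post <- tissue_volumes(seg_post, vox_vol)
  volumes <- tibble::tibble(
    tissue = c("csf", "gm", "wm"),
    pre_ml = as.numeric(tv_pre[1, ]),
    post_ml = as.numeric(tv_post[1, ]),
    pct_change = percent_volume_change(as.numeric(tv_pre[1, ]),
                                       as.numeric(tv_post[1, ]))
  )
  edges <- edge_displacement(vol_pre, vol_post, brain_mask, voxel_size)
  vc <- pbvc(edges, sum(brain_mask) * vox_vol)
  list(volumes = volumes, pbvc = vc, edges = edges,
       seg_pre = seg_pre, seg_post = seg_post)
}
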