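# Geometry helpers -----------------------------------------------------------

# normalized ellipsoid radius (1 at the surface) on a voxel grid; voxel centres
# sit at (i - 0.5) * voxel_size mm
ellipsoid_rho <- function(dims, voxel_size, center_mm, semiaxes_mm) {
  ax <- lapply(1:3, function(i) {
    (((seq_len(dims[i]) - 0.5) * voxel_size[i]) - center_mm[i]) / semiaxes_mm[i]
  })
  x2 <- array(ax[[1]]^2, dims)
  y2 <- aperm(array(ax[[2]]^2, dims[c(2, 1, 3)]), c(2, 1, 3))
  z2 <- aperm(array(ax[[3]]^2, dims[c(3, 1, 2)]), c(2, 3, 1))
  sqrt(x2 + y2 + z2)
}

# clamp into [0, 1] without losing array dims (pmax(0, x) would)
clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# approximate signed distance (mm, positive outside) from normalized radius
ellipsoid_signed_distance <- function(rho, semiaxes_mm) {
  (rho - 1) * exp(mean(log(semiaxes_mm)))
}

voxel_grid_mm <- function(dims, voxel_size) {
  list(
    x = (seq_len(dims[1]) - 0.5) * voxel_size[1],
    y = (seq_len(dims[2]) - 0.5) * voxel_size[2],
    z = (seq_len(dims[3]) - 0.5) * voxel_size[3]
  )
}

sphere_mask <- function(dims, voxel_size, center_mm, radius_mm) {
  rho <- ellipsoid_rho(dims, voxel_size, center_mm, rep(radius_mm, 3))
  rho <= 1
}

# BOLD phantom ----------------------------------------------------------------

#' Specify a BOLD reactivity phantom
#'
#' Builds a three-compartment elliptical "brain" (CSF shell, gray-matter shell,
#' white-matter core) on a voxel grid, with a ground-truth CVR map (gray matter
#' about twice white matter, the pattern seen in vivo), optional scattered
#' negative-CVR foci emulating vascular steal, a hemodynamic/sampling delay
#' map, and per-tissue baseline signal levels.
#'
#' @param dims Grid size per axis, voxels.
#' @param voxel_size Voxel size per axis, mm.
#' @param gm_cvr,wm_cvr True CVR in gray and white matter, percent per mmHg.
#' @param n_neg_foci Number of spherical negative-CVR foci seeded in gray
#'   matter.
#' @param neg_cvr CVR value inside the negative foci, percent per mmHg
#'   (negative).
#' @param focus_radius_mm Radius of each negative focus, mm.
#' @param csf_thickness_mm,gm_thickness_mm Shell thicknesses, mm; on grids too
#'   small to hold them the white-matter core is kept at a quarter of the
#'   brain radius.
#' @param delay_s Uniform hemodynamic plus gas-sampling delay between the
#'   petCO2 stimulus and the BOLD response, seconds.
#' @param baseline Named vector of baseline signal levels (arbitrary units)
#'   for `csf`, `gm`, `wm`.
#' @param noise_sd Gaussian noise standard deviation, same units as baseline.
#' @param drift_amplitude Peak-to-peak linear drift over the run, same units.
#' @param seed Integer seed used when seeding foci.
#' @return An object of class `bold_phantom_spec` carrying the label volume
#'   (0 background, 1 CSF, 2 GM, 3 WM), `true_cvr`, `delay` and
#'   `baseline_signal` arrays.
#' @export
bold_phantom_spec <- function(dims = c(40, 48, 40),
                              voxel_size = c(3, 3, 3),
                              gm_cvr = 0.30,
                              wm_cvr = 0.15,
                              n_neg_foci = 3,
                              neg_cvr = -0.20,
                              focus_radius_mm = 7.5,
                              csf_thickness_mm = 6,
                              gm_thickness_mm = 18,
                              delay_s = 6,
                              baseline = c(csf = 500, gm = 1000, wm = 900),
                              noise_sd = 10,
                              drift_amplitude = 0,
                              seed = 1L) {
  stopifnot(length(dims) == 3, length(voxel_size) == 3, delay_s >= 0)
  extent <- dims * voxel_size
  center <- extent / 2
  outer <- extent / 2 - 2 * voxel_size        # brain outer surface
  edge <- min(voxel_size)
  gm_ax <- pmax(outer - csf_thickness_mm, 0.5 * outer)
  wm_ax <- pmax(gm_ax - gm_thickness_mm, 0.25 * outer)
  rho <- ellipsoid_rho(dims, voxel_size, center, outer)
  d_brain <- ellipsoid_signed_distance(rho, outer)
  d_gm <- ellipsoid_signed_distance(
    ellipsoid_rho(dims, voxel_size, center, gm_ax), gm_ax
  )
  d_wm <- ellipsoid_signed_distance(
    ellipsoid_rho(dims, voxel_size, center, wm_ax), wm_ax
  )
  labels <- array(0L, dims)
  labels[d_brain <= 0] <- 1L   # CSF shell
  labels[d_gm <= 0] <- 2L      # gray matter shell
  labels[d_wm <= 0] <- 3L      # white matter core

  true_cvr <- array(0, dims)
  true_cvr[labels == 2L] <- gm_cvr
  true_cvr[labels == 3L] <- wm_cvr

  focus_centers <- NULL
  if (n_neg_foci > 0) {
    set.seed(as.integer(seed))
    gm_idx <- which(labels == 2L & d_gm > -12)  # outer part of the GM shell
    grid <- voxel_grid_mm(dims, voxel_size)
    picks <- integer(0)
    coords_of <- function(i) {
      ijk <- arrayInd(i, dims)
      c(grid$x[ijk[1]], grid$y[ijk[2]], grid$z[ijk[3]])
    }
    guard <- 0
    while (length(picks) < n_neg_foci && guard < 1000) {
      guard <- guard + 1
      cand <- sample(gm_idx, 1)
      ok <- TRUE
      for (p in picks) {
        if (sqrt(sum((coords_of(cand) - coords_of(p))^2)) < 3 * focus_radius_mm) {
          ok <- FALSE
          break
        }
      }
      if (ok) picks <- c(picks, cand)
    }
    focus_centers <- t(vapply(picks, coords_of, numeric(3)))
    for (k in seq_len(nrow(focus_centers))) {
      sm <- sphere_mask(dims, voxel_size, focus_centers[k, ], focus_radius_mm)
      true_cvr[sm & labels == 2L] <- neg_cvr
    }
  }

  baseline_signal <- array(0, dims)
  baseline_signal[labels == 1L] <- baseline[["csf"]]
  baseline_signal[labels == 2L] <- baseline[["gm"]]
  baseline_signal[labels == 3L] <- baseline[["wm"]]

  structure(
    list(
      dims = dims, voxel_size = voxel_size,
      labels = labels, true_cvr = true_cvr,
      delay = array(delay_s, dims),
      baseline_signal = baseline_signal,
      noise_sd = noise_sd, drift_amplitude = drift_amplitude,
      focus_centers = focus_centers, seed = as.integer(seed)
    ),
    class = "bold_phantom_spec"
  )
}

#' Simulate a 4D BOLD series from a phantom and a petCO2 schedule
#'
#' The signal model is a pure linear BOLD response to the petCO2 change,
#' delayed voxelwise:
#' `S(v,t) = S0(v) * (1 + CVR(v)/100 * dpetCO2(t - delay(v))) + drift(t) + noise`.
#' No hemodynamic response function beyond the pure delay is modelled, and the
#' phantom is motion-free.
#'
#' @param spec A [bold_phantom_spec()].
#' @param schedule Tibble with `time` (mid-volume, s) and `delta_petco2`
#'   (mmHg), e.g. from [protocol_volume_schedule()].
#' @param tr Repetition time, seconds.
#' @param seed Integer seed for noise; the same seed gives a bit-identical
#'   series.
#' @return A [bold_series()] whose `truth` element records the ground-truth
#'   CVR, delay and tissue labels.
#' @export
generate_bold_phantom <- function(spec, schedule, tr = 2, seed = 1L) {
  stopifnot(inherits(spec, "bold_phantom_spec"))
  n_vol <- nrow(schedule)
  if (n_vol < 2) stop("schedule must cover at least two volumes")
  set.seed(as.integer(seed))
  dims <- spec$dims
  n_vox <- prod(dims)
  mask <- spec$labels > 0L

  # stepwise stimulus sampled at shifted times; constant interpolation keeps
  # integer-volume delays exact
  delta_at <- function(tt) {
    stats::approx(schedule$time, schedule$delta_petco2, xout = tt,
                  method = "constant", f = 0, rule = 2)$y
  }
  delays <- unique(as.vector(spec$delay[mask]))
  t_mid <- schedule$time

  data <- array(0, c(dims, n_vol))
  s0 <- as.vector(spec$baseline_signal)
  cvr <- as.vector(spec$true_cvr)
  dl <- as.vector(spec$delay)
  flat <- matrix(0, n_vox, n_vol)
  for (d in delays) {
    sel <- which(as.vector(mask) & dl == d)
    shifted <- delta_at(t_mid - d)
    flat[sel, ] <- outer(s0[sel], rep(1, n_vol)) *
      (1 + outer(cvr[sel] / 100, shifted))
  }
  if (spec$drift_amplitude != 0) {
    drift <- spec$drift_amplitude * (seq_len(n_vol) - 1) / (n_vol - 1)
    flat[as.vector(mask), ] <- flat[as.vector(mask), ] +
      matrix(drift, sum(mask), n_vol, byrow = TRUE)
  }
  if (spec$noise_sd > 0) {
    msk <- which(as.vector(mask))
    flat[msk, ] <- flat[msk, ] +
      matrix(stats::rnorm(length(msk) * n_vol, 0, spec$noise_sd),
             length(msk), n_vol)
  }
  data <- array(flat, c(dims, n_vol))

  bold_series(
    data, tr = tr, voxel_size = spec$voxel_size, mask = mask,
    truth = list(
      cvr = spec$true_cvr, delay = spec$delay, labels = spec$labels,
      focus_centers = spec$focus_centers
    )
  )
}

# Structural phantom ----------------------------------------------------------

#' Specify a structural (T1-like) brain phantom
#'
#' Same three-compartment elliptical geometry as the BOLD phantom but with
#' sub-voxel partial-volume boundaries, T1-like tissue contrast
#' (CSF < GM < WM) and optional intensity noise.
#'
#' @param dims,voxel_size Grid geometry (voxels; mm).
#' @param semiaxes_mm Outer brain semiaxes, mm; a single value gives a sphere.
#' @param csf_thickness_mm,gm_thickness_mm Shell thicknesses, mm.
#' @param intensity Named vector of mean tissue intensities for `csf`, `gm`,
#'   `wm` (arbitrary units).
#' @param noise_sd Gaussian intensity noise SD, same units.
#' @param edge_mm Width of the linear partial-volume ramp at each tissue
#'   interface, mm. The default of one voxel mimics scanner partial
#'   voluming and gives the sub-voxel boundaries edge displacement needs;
#'   `0` produces hard-labelled three-level volumes whose voxel counts are
#'   exact.
#' @return An object of class `structural_phantom_spec`.
#' @export
structural_phantom_spec <- function(dims = c(96, 96, 96),
                                    voxel_size = c(2, 2, 2),
                                    semiaxes_mm = c(78, 88, 72),
                                    csf_thickness_mm = 8,
                                    gm_thickness_mm = 18,
                                    intensity = c(csf = 250, gm = 650, wm = 1000),
                                    noise_sd = 0,
                                    edge_mm = min(voxel_size)) {
  if (length(semiaxes_mm) == 1) semiaxes_mm <- rep(semiaxes_mm, 3)
  extent <- dims * voxel_size
  if (any(2 * semiaxes_mm > extent - 2 * voxel_size)) {
    stop("phantom does not fit in the grid")
  }
  structure(
    list(
      dims = dims, voxel_size = voxel_size, semiaxes_mm = semiaxes_mm,
      csf_thickness_mm = csf_thickness_mm, gm_thickness_mm = gm_thickness_mm,
      intensity = intensity, noise_sd = noise_sd, edge_mm = edge_mm
    ),
    class = "structural_phantom_spec"
  )
}

#' @rdname generate_structural_pair
#' @param tissue_scale Named per-tissue volumetric scale factors (`gm`, `wm`);
#'   e.g. `c(gm = 0.974)` imposes a 2.6 percent gray-matter loss. Atrophy is
#'   geometric: the tissue's bounding interface is moved by the amount that
#'   changes its volume by the requested factor (WM across the GM/WM
#'   interface, GM across the cortical surface with CSF replacing it), so a
#'   segmentation of the follow-up image genuinely sees less tissue.
#' @param boundary_shift_mm Signed displacement of the outer brain surface,
#'   mm; negative shrinks the brain (atrophy).
#' @export
atrophy_spec <- function(tissue_scale = c(gm = 1, wm = 1),
                         boundary_shift_mm = 0) {
  ts <- c(gm = 1, wm = 1)
  ts[names(tissue_scale)] <- tissue_scale
  if (any(ts <= 0)) stop("tissue_scale must be positive")
  structure(list(tissue_scale = ts, boundary_shift_mm = boundary_shift_mm),
            class = "atrophy_spec")
}

#' @rdname generate_structural_pair
#' @param n_lesions Number of white-matter lesions to seed.
#' @param radius_range_mm Lesion radius range, mm.
#' @export
lesion_spec <- function(n_lesions = 0, radius_range_mm = c(2, 5)) {
  if (n_lesions < 0) stop("n_lesions must be >= 0")
  if (any(radius_range_mm <= 0)) stop("radii must be positive")
  structure(list(n_lesions = n_lesions, radius_range_mm = radius_range_mm),
            class = "lesion_spec")
}

# partial-volume maps of a structural phantom; the three nested surfaces can
# be shifted independently (mm, positive = outward) to impose atrophy
structural_pv <- function(spec, outer_shift = 0, gm_shift = 0, wm_shift = 0) {
  dims <- spec$dims
  vs <- spec$voxel_size
  extent <- dims * vs
  center <- extent / 2
  edge <- spec$edge_mm
  sd_at <- function(ax) {
    ellipsoid_signed_distance(ellipsoid_rho(dims, vs, center, ax), ax)
  }
  pv_ramp <- if (edge > 0) {
    function(dist_mm) clamp01(0.5 - dist_mm / edge)
  } else {
    function(dist_mm) (dist_mm < 0) + 0
  }
  outer <- spec$semiaxes_mm + outer_shift
  gm_out <- spec$semiaxes_mm - spec$csf_thickness_mm + outer_shift + gm_shift
  wm_out <- spec$semiaxes_mm - spec$csf_thickness_mm - spec$gm_thickness_mm +
    outer_shift + wm_shift
  pv_brain <- pv_ramp(sd_at(outer))
  pv_gm_out <- pv_ramp(sd_at(gm_out))
  pv_wm <- pv_ramp(sd_at(wm_out))
  list(
    csf = clamp01(pv_brain - pv_gm_out),
    gm = clamp01(pv_gm_out - pv_wm),
    wm = pv_wm,
    brain = pv_brain
  )
}

structural_intensity <- function(spec, pv) {
  spec$intensity[["csf"]] * pv$csf +
    spec$intensity[["gm"]] * pv$gm +
    spec$intensity[["wm"]] * pv$wm
}

#' Generate a paired structural phantom with known atrophy and lesions
#'
#' Time point 1 is the phantom as specified; time point 2 applies the atrophy:
#' the outer brain surface is displaced along its normal by
#' `boundary_shift_mm` (regenerating the geometry with shifted semiaxes, so
#' the displacement is exact) and/or per-tissue partial volumes are rescaled,
#' with the lost tissue fraction converted to CSF. Ground-truth tissue volumes
#' (mL) at both time points and the lesion count are returned alongside.
#'
#' @param spec A [structural_phantom_spec()].
#' @param atrophy An [atrophy_spec()].
#' @param lesions A [lesion_spec()]; lesions are seeded in deep white matter
#'   and returned as a binary mask (they do not alter the T1-like volumes).
#' @param seed Integer seed for noise and lesion placement.
#' @return List with `vol1`, `vol2` (3D intensity arrays), `brain_mask`,
#'   `lesion_mask`, `voxel_size` and a `truth` list (`volumes` tibble in mL by
#'   session and tissue, `n_lesions`, the atrophy parameters).
#' @export
generate_structural_pair <- function(spec,
                                     atrophy = atrophy_spec(),
                                     lesions = lesion_spec(),
                                     seed = 1L) {
  stopifnot(inherits(spec, "structural_phantom_spec"),
            inherits(atrophy, "atrophy_spec"),
            inherits(lesions, "lesion_spec"))
  if (abs(atrophy$boundary_shift_mm) >= min(spec$semiaxes_mm)) {
    stop("boundary_shift larger than object radius")
  }
  set.seed(as.integer(seed))
  vox_ml <- prod(spec$voxel_size) / 1000

  pv1 <- structural_pv(spec)
  sc <- atrophy$tissue_scale
  os <- atrophy$boundary_shift_mm
  # move the WM interface, then the cortical surface, to hit the volume
  # targets exactly (root-find on the interface shift)
  if (any(sc != 1) && spec$edge_mm <= 0) {
    stop("tissue_scale atrophy needs a partial-volume ramp (edge_mm > 0) ",
         "for the interface shift to be solvable")
  }
  wm_shift <- 0
  if (sc[["wm"]] != 1) {
    target <- sc[["wm"]] * sum(structural_pv(spec, os, 0, 0)$wm)
    wm_shift <- stats::uniroot(
      function(s) sum(structural_pv(spec, os, 0, s)$wm) - target,
      interval = c(-0.9, 0.9) * spec$gm_thickness_mm, tol = 1e-4
    )$root
  }
  gm_shift <- 0
  if (sc[["gm"]] != 1) {
    target <- sc[["gm"]] * sum(structural_pv(spec, os, 0, wm_shift)$gm)
    gm_shift <- stats::uniroot(
      function(s) sum(structural_pv(spec, os, s, wm_shift)$gm) - target,
      interval = c(-0.9, 0.9) * spec$gm_thickness_mm, tol = 1e-4
    )$root
  }
  pv2 <- structural_pv(spec, os, gm_shift, wm_shift)

  vol1 <- structural_intensity(spec, pv1)
  vol2 <- structural_intensity(spec, pv2)
  if (spec$noise_sd > 0) {
    vol1 <- vol1 + array(stats::rnorm(length(vol1), 0, spec$noise_sd), dim(vol1))
    vol2 <- vol2 + array(stats::rnorm(length(vol2), 0, spec$noise_sd), dim(vol2))
  }

  lesion_mask <- array(FALSE, spec$dims)
  if (lesions$n_lesions > 0) {
    wm_deep <- which(pv1$wm > 0.99)
    grid <- voxel_grid_mm(spec$dims, spec$voxel_size)
    coords_of <- function(i) {
      ijk <- arrayInd(i, spec$dims)
      c(grid$x[ijk[1]], grid$y[ijk[2]], grid$z[ijk[3]])
    }
    rmax <- max(lesions$radius_range_mm)
    centers <- matrix(numeric(0), 0, 3)
    guard <- 0
    while (nrow(centers) < lesions$n_lesions && guard < 5000) {
      guard <- guard + 1
      cand <- coords_of(sample(wm_deep, 1))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >
            2 * rmax + 2 * max(spec$voxel_size)) {
        centers <- rbind(centers, cand)
      }
    }
    if (nrow(centers) < lesions$n_lesions) {
      stop("could not place the requested number of disjoint lesions")
    }
    radii <- stats::runif(lesions$n_lesions, lesions$radius_range_mm[1],
                          lesions$radius_range_mm[2])
    for (k in seq_len(lesions$n_lesions)) {
      lesion_mask <- lesion_mask |
        sphere_mask(spec$dims, spec$voxel_size, centers[k, ], radii[k])
    }
  }

  truth_vol <- tibble::tibble(
    session = rep(c("pre", "post"), each = 3),
    tissue = rep(c("csf", "gm", "wm"), 2),
    volume_ml = c(sum(pv1$csf), sum(pv1$gm), sum(pv1$wm),
                  sum(pv2$csf), sum(pv2$gm), sum(pv2$wm)) * vox_ml
  )

  list(
    vol1 = vol1, vol2 = vol2,
    brain_mask = pv1$brain > 0.5,
    lesion_mask = lesion_mask,
    voxel_size = spec$voxel_size,
    truth = list(
      volumes = truth_vol,
      n_lesions = lesions$n_lesions,
      tissue_scale = atrophy$tissue_scale,
      boundary_shift_mm = atrophy$boundary_shift_mm
    )
  )
}

# Phantom atlas ---------------------------------------------------------------

#' Integer-label phantom atlas with subcortical structures
#'
#' Builds an atlas on the BOLD phantom grid with the ten structures used for
#' regional CVR reporting: gray matter, white matter, brainstem (no
#' hemisphere), and bilateral accumbens, amygdala, caudate, hippocampus,
#' pallidum, putamen and thalamus as spheres placed symmetrically about the
#' midline inside the deep phantom brain. Subcortical labels override the
#' tissue labels where they overlap.
#'
#' @param spec A [bold_phantom_spec()] defining the grid and tissue labels.
#' @param radius_mm Radius of each subcortical sphere, mm.
#' @return List with `labels` (integer array) and `lut`, a tibble mapping
#'   `id` to `structure` and `hemisphere` (`left`, `right` or `none`).
#' @export
phantom_atlas <- function(spec, radius_mm = 9) {
  stopifnot(inherits(spec, "bold_phantom_spec"))
  dims <- spec$dims
  vs <- spec$voxel_size
  extent <- dims * vs
  c0 <- extent / 2
  labels <- array(0L, dims)
  labels[spec$labels == 2L] <- 1L
  labels[spec$labels == 3L] <- 2L
  lut <- tibble::tibble(
    id = 1:2, structure = c("gray_matter", "white_matter"),
    hemisphere = "none"
  )
  structures <- c("accumbens", "amygdala", "caudate", "hippocampus",
                  "pallidum", "putamen", "thalamus")
  # deep positions: offsets (mm) from grid centre, mirrored in x for the two
  # hemispheres
  offs <- list(
    accumbens = c(12, 18, -6), amygdala = c(22, 10, -10),
    caudate = c(12, 8, 8), hippocampus = c(24, -8, -4),
    pallidum = c(14, -2, 0), putamen = c(20, 2, 2),
    thalamus = c(8, -6, 4)
  )
  next_id <- 3L
  for (s in structures) {
    for (hemi in c("left", "right")) {
      sgn <- if (hemi == "left") -1 else 1
      ctr <- c0 + c(sgn * offs[[s]][1], offs[[s]][2], offs[[s]][3])
      m <- sphere_mask(dims, vs, ctr, radius_mm) & spec$labels > 0L
      labels[m] <- next_id
      lut <- dplyr::bind_rows(lut, tibble::tibble(
        id = next_id, structure = s, hemisphere = hemi
      ))
      next_id <- next_id + 1L
    }
  }
  bs <- sphere_mask(dims, vs, c0 + c(0, -14, -14), radius_mm + 3) &
    spec$labels > 0L
  labels[bs] <- next_id
  lut <- dplyr::bind_rows(lut, tibble::tibble(
    id = next_id, structure = "brainstem", hemisphere = "none"
  ))
  list(labels = labels, lut = lut)
}
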