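#' Mean CVR over a mask or atlas
#'
#' `extract_region_cvr` averages a CVR map over one mask; `region_cvr`
#' applies it to every structure of an integer-label atlas and returns a tidy
#' table.
#'
#' @param cvr_map A [cvr_from_glm()] result (or any list with `cvr` and
#'   `mask`).
#' @param mask Logical array delimiting the region.
#' @param structure,hemisphere,session Labels carried into the output row.
#' @return One-row tibble: `structure`, `hemisphere`, `session`, `mean_cvr`,
#'   `n_voxels`.
#' @export
extract_region_cvr <- function(cvr_map, mask, structure = "region",
                               hemisphere = "none", session = "pre") {
  m <- mask & cvr_map$mask
  if (!any(m)) stop("empty region mask")
  tibble::tibble(
    structure = structure, hemisphere = hemisphere, session = session,
    mean_cvr = mean(cvr_map$cvr[m]), n_voxels = sum(m)
  )
}

#' @rdname extract_region_cvr
#' @param atlas List with `labels` (integer array) and `lut` (tibble `id`,
#'   `structure`, `hemisphere`), e.g. from [phantom_atlas()] or
#'   [read_atlas()].
#' @export
region_cvr <- function(cvr_map, atlas, session = "pre") {
  purrr::pmap(atlas$lut, function(id, structure, hemisphere) {
    m <- atlas$labels == id
    if (!any(m & cvr_map$mask)) return(NULL)
    extract_region_cvr(cvr_map, m, structure, hemisphere, session)
  }) |>
    dplyr::bind_rows()
}

#' Read an integer-label atlas volume and its label table
#'
#' @param labels_path NIfTI path of the integer label volume.
#' @param lut_path CSV with columns `id`, `structure`, `hemisphere`.
#' @return List with `labels` and `lut` as used by [region_cvr()].
#' @export
read_atlas <- function(labels_path, lut_path) {
  labels <- read_volume(labels_path)
  storage.mode(labels) <- "integer"
  lut <- tibble::as_tibble(utils::read.csv(lut_path))
  missing <- setdiff(unique(labels[labels > 0]), lut$id)
  if (length(missing)) {
    stop("labels in volume missing from table: ", paste(missing, collapse = ", "))
  }
  list(labels = labels, lut = lut)
}

#' Split a structure into pre-test positive- and negative-CVR compartments
#'
#' A structure's mean CVR can hide focal vascular steal, so each structure is
#' dichotomized at pre-test into the voxels with significant positive CVR and
#' those with significant negative CVR. Voxels with CVR exactly zero belong
#' to neither (a measure-zero event under noise; the rule keeps the split
#' deterministic). A compartment with no voxels is recorded as absent.
#'
#' @param pre_map Pre-test CVR map ([cvr_from_glm()] result).
#' @param pre_sig Pre-test significance mask (see [significant_mask()]).
#' @param structure_mask Logical array for the structure.
#' @param structure Structure name carried through.
#' @return List of class `dichotomy_masks`: logical arrays `positive` and
#'   `negative` (or `NULL` when empty), `structure`, and voxel counts.
#' @export
dichotomize <- function(pre_map, pre_sig, structure_mask,
                        structure = "region") {
  base <- structure_mask & pre_sig & pre_map$mask
  pos <- base & pre_map$cvr > 0
  neg <- base & pre_map$cvr < 0
  structure(
    list(
      structure = structure,
      positive = if (any(pos)) pos else NULL,
      negative = if (any(neg)) neg else NULL,
      n_positive = sum(pos), n_negative = sum(neg)
    ),
    class = "dichotomy_masks"
  )
}

#' Extract compartment means at both sessions from fixed pre-test masks
#'
#' The pre-test compartment masks are frozen and applied unchanged to the
#' follow-up map, so any change in a compartment's mean reflects a change in
#' the same voxels, not a change in mask membership. Absent compartments
#' propagate as absent (no rows).
#'
#' @param pre_map,post_map CVR maps at the two sessions, same grid.
#' @param masks A [dichotomize()] result.
#' @return Tibble with columns `structure`, `compartment` (`positive` /
#'   `negative`), `session` (`pre` / `post`), `mean_cvr`, `n_voxels`.
#' @export
apply_masks_at_followup <- function(pre_map, post_map, masks) {
  stopifnot(inherits(masks, "dichotomy_masks"))
  rows <- list()
  for (cmp in c("positive", "negative")) {
    m <- masks[[cmp]]
    if (is.null(m)) next
    for (ses in c("pre", "post")) {
      mp <- if (ses == "pre") pre_map else post_map
      rows[[length(rows) + 1]] <- tibble::tibble(
        structure = masks$structure, compartment = cmp, session = ses,
        mean_cvr = mean(mp$cvr[m & mp$mask]), n_voxels = sum(m & mp$mask)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Fractional frequency distribution of CVR over a mask
#'
#' Histogram of the masked CVR values normalized to fractions (summing to 1),
#' with the distribution mean recorded for the usual vertical marker. A
#' rightward shift of the mean between sessions summarizes the loss of
#' negative-CVR voxels.
#'
#' @param cvr_map A CVR map.
#' @param mask Logical array.
#' @param bin_width Bin width in percent per mmHg.
#' @param range Histogram range (values outside are clamped into the end
#'   bins).
#' @return Tibble of class `cvr_distribution`: `bin_lower`, `bin_upper`,
#'   `bin_mid`, `fraction`; the mean is in the `mean_cvr` attribute.
#' @export
fractional_distribution <- function(cvr_map, mask, bin_width = 0.025,
                                    range = c(-1, 1)) {
  m <- mask & cvr_map$mask
  if (!any(m)) stop("empty mask")
  v <- cvr_map$cvr[m]
  edges <- seq(range[1], range[2], by = bin_width)
  if (edges[length(edges)] < range[2]) edges <- c(edges, range[2])
  vc <- pmin(pmax(v, range[1] + 1e-12), range[2] - 1e-12)
  counts <- tabulate(findInterval(vc, edges), nbins = length(edges) - 1)
  out <- tibble::tibble(
    bin_lower = edges[-length(edges)],
    bin_upper = edges[-1],
    bin_mid = (edges[-length(edges)] + edges[-1]) / 2,
    fraction = counts / sum(counts)
  )
  attr(out, "mean_cvr") <- mean(v)
  class(out) <- c("cvr_distribution", class(out))
  out
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a fractional CVR distribution
#'
#' Bar histogram of voxel fractions with a dashed vertical line at the
#' distribution mean.
#'
#' @param object A [fractional_distribution()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cvr_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$fraction)) +
    ggplot2::geom_col(width = object$bin_upper[1] - object$bin_lower[1],
                      fill = "grey40") +
    ggplot2::geom_vline(xintercept = attr(object, "mean_cvr"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(CVR ~ ("%" ~ mmHg^-1)),
                  y = "Fraction of voxels") +
    ggplot2::theme_minimal()
}

#' Percent change between paired measurements
#'
#' `100 * (post - pre) / pre`, sign preserving; errors on a zero baseline.
#'
#' @param pre,post Numeric vectors (recycled pairwise).
#' @return Percent change(s).
#' @examples
#' percent_change(0.30, 0.39)  # +30
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) stop("percent change undefined for zero baseline")
  100 * (post - pre) / pre
}
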