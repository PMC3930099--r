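#' Goodness-of-fit of a component map to a template mask
#'
#' Z-scores the component map over the analysis-mask voxels and returns
#' the mean Z inside the binary template minus the mean Z outside it.
#' A map that loads preferentially on the template's voxels scores
#' high; the score is invariant to positive affine rescaling of the map
#' and flips sign under map negation.
#'
#' @param map numeric array (component loadings).
#' @param template binary array on the same grid (the network mask).
#' @param analysis_mask optional binary array restricting both the
#'   Z-scoring and the in/out means (e.g. a brain mask); \code{NULL}
#'   uses all voxels.
#' @param variance \code{"population"} (divide by N; default) or
#'   \code{"sample"} (divide by N - 1) Z-scoring.
#' @return scalar GOF score (unitless).
#' @export
gof_score <- function(map, template, analysis_mask = NULL,
                      variance = c("population", "sample")) {
  variance <- match.arg(variance)
  if (!identical(dim(map) %||% length(map), dim(template) %||% length(template)))
    stop("map and template grids do not match", call. = FALSE)
  keep <- if (is.null(analysis_mask)) rep(TRUE, length(map)) else {
    if (!identical(dim(analysis_mask) %||% length(analysis_mask),
                   dim(map) %||% length(map)))
      stop("analysis mask grid does not match the map", call. = FALSE)
    as.logical(analysis_mask != 0)
  }
  v <- as.numeric(map)[keep]
  stop_if_not_finite(v, "component map (within analysis mask)")
  inmask <- as.logical(template != 0)[keep]
  if (!any(inmask) || all(inmask))
    stop("template must have voxels both inside and outside the mask ",
         "within the analysis mask", call. = FALSE)
  n <- length(v)
  s2 <- stats::var(v) * (if (variance == "population") (n - 1) / n else 1)
  if (s2 == 0)
    stop("all-constant map: Z-scoring undefined", call. = FALSE)
  z <- (v - mean(v)) / sqrt(s2)
  mean(z[inmask]) - mean(z[!inmask])
}

#' Rank component maps against a template and select one
#'
#' Ranks all candidate maps by GOF with the target template
#' (descending; ties broken toward the lower map index and logged) and
#' selects the best-ranked component that is not captured by an artifact
#' template: a component is skipped whenever its GOF with any exclusion
#' template (e.g. a cerebrospinal-fluid mask) exceeds its GOF with the
#' target. Every skip is recorded.
#'
#' @param maps list of component maps (shared grid).
#' @param template target binary template array.
#' @param exclusion_templates list of artifact templates (may be empty).
#' @param analysis_mask optional binary array, see [gof_score()].
#' @param ... passed to [gof_score()].
#' @return object of class \code{gof_ranking}: list with \code{scores}
#'   (data.frame: component, gof, excluded — sorted by gof descending),
#'   \code{selected} (component index into \code{maps}), and
#'   \code{notes} (character log of skips and ties).
#' @export
rank_and_select <- function(maps, template, exclusion_templates = list(),
                            analysis_mask = NULL, ...) {
  stopifnot(is.list(maps), length(maps) >= 2L)
  gof <- vapply(maps, gof_score, numeric(1), template = template,
                analysis_mask = analysis_mask, ...)
  excl <- vapply(seq_along(maps), function(i) {
    if (length(exclusion_templates) == 0L) return(FALSE)
    ex <- vapply(exclusion_templates, function(tpl)
      gof_score(maps[[i]], tpl, analysis_mask = analysis_mask, ...),
      numeric(1))
    any(ex > gof[i])
  }, logical(1))
  ord <- order(-gof, seq_along(gof))   # ties -> lower component index
  notes <- character(0)
  if (anyDuplicated(gof))
    notes <- c(notes, "tied GOF scores broken toward the lower component index")
  sel <- NA_integer_
  for (i in ord) {
    if (!excl[i]) { sel <- i; break }
    notes <- c(notes, sprintf(
      "component %d skipped: better fit with an exclusion template (GOF %.4f)",
      i, gof[i]))
  }
  if (is.na(sel))
    stop("all components excluded by artifact templates", call. = FALSE)
  structure(list(
    scores = data.frame(component = ord, gof = gof[ord],
                        excluded = excl[ord]),
    selected = sel, notes = notes), class = "gof_ranking")
}

#' @export
print.gof_ranking <- function(x, ...) {
  cat(sprintf("GOF ranking of %d components; selected component %d (GOF %.4f)\n",
              nrow(x$scores), x$selected,
              x$scores$gof[x$scores$component == x$selected]))
  if (length(x$notes)) cat(paste0("  ", x$notes, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a NIfTI volume as a plain array
#'
#' Thin wrapper over \pkg{RNifti} for template masks and component maps.
#' @param path NIfTI file path.
#' @return numeric array.
#' @export
read_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package", call. = FALSE)
  as.array(RNifti::readNifti(path))
}

#' Write a plain array as a NIfTI volume
#' @param x numeric array.
#' @param path output path.
#' @param pixdim voxel dimensions (mm), recycled to 3.
#' @export
write_volume <- function(x, path, pixdim = c(3.4, 3.4, 3.4)) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI volumes requires the RNifti package", call. = FALSE)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- rep_len(pixdim, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}
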