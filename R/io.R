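#' Write a cohort to disk as plain-text files plus a manifest
#'
#' One tab-separated time-course file per subject (header row of network
#' names, one row per volume), one whitespace-delimited 6-column
#' realignment file per subject, and a JSON-lines manifest
#' (\code{cohort.jsonl}) carrying subject id, group, covariates, file
#' names and the sampling interval.
#'
#' @param cohort a \code{cohort}.
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(dir, "cohort.jsonl")
  con <- file(manifest, "w")
  on.exit(close(con))
  for (s in cohort$subjects) {
    tc_file <- paste0(s$id, "_timecourses.tsv")
    rp_file <- paste0("rp_", s$id, ".txt")
    tc <- t(s$timecourses)                     # rows = volumes
    colnames(tc) <- paste0("net", seq_len(ncol(tc)))
    utils::write.table(tc, file.path(dir, tc_file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_realignment(s$realignment, file.path(dir, rp_file))
    writeLines(jsonlite::toJSON(list(
      id = s$id, group = s$group,
      timecourses = tc_file, realignment = rp_file,
      sampling_interval = cohort$sampling_interval,
      covariates = s$covariates), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#' @param manifest path to the \code{cohort.jsonl} manifest.
#' @return a \code{cohort}.
#' @export
read_cohort <- function(manifest) {
  dir <- dirname(manifest)
  lines <- readLines(manifest)
  subjects <- lapply(lines, function(l) {
    m <- jsonlite::fromJSON(l)
    tc <- as.matrix(utils::read.table(file.path(dir, m$timecourses),
                                      header = TRUE, sep = "\t"))
    list(id = m$id, group = m$group,
         timecourses = t(tc),
         realignment = read_realignment(file.path(dir, m$realignment)),
         covariates = m$covariates)
  })
  si <- jsonlite::fromJSON(lines[1])$sampling_interval
  structure(list(subjects = subjects, sampling_interval = si,
                 groups = unique(vapply(subjects, `[[`, character(1),
                                        "group"))),
            class = "cohort")
}

#' Read a 6-column realignment-parameter file
#'
#' Whitespace-delimited text, one row per volume: x, y, z translations
#' (mm) then rotations about x, y, z (radians) — the common
#' realignment-parameter layout.
#'
#' @param path file path.
#' @return T-by-6 numeric matrix.
#' @export
read_realignment <- function(path) {
  rp <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(rp) != 6L)
    stop("expected 6 columns of realignment parameters, got ", ncol(rp),
         call. = FALSE)
  colnames(rp) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rp
}

#' @rdname read_realignment
#' @param rp T-by-6 matrix to write.
#' @export
write_realignment <- function(rp, path) {
  utils::write.table(format(rp, digits = 10, scientific = TRUE),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write per-subject GPDC spectra as a long-format TSV
#'
#' Columns: subject, source, target, bin_hz, value — one row per
#' ordered path and frequency bin (diagonal terms omitted).
#'
#' @param spectra list of \code{gpdc_spectrum}, named by subject id (or
#'   positional ids are generated).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gpdc_tsv <- function(spectra, path) {
  ids <- names(spectra) %||% sprintf("sub-%03d", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(s) {
    g <- spectra[[s]]
    k <- dim(g$values)[1]
    idx <- which(row(diag(k)) != col(diag(k)), arr.ind = TRUE)
    do.call(rbind, lapply(seq_along(g$bins), function(b)
      data.frame(subject = ids[s], source = idx[, 2], target = idx[, 1],
                 bin_hz = g$bins[b],
                 value = g$values[, , b][idx],
                 stringsAsFactors = FALSE)))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read GPDC spectra from a long-format TSV written by [write_gpdc_tsv()]
#' @param path TSV path.
#' @param squared whether the stored values are squared moduli.
#' @param sampling_interval seconds per sample recorded on the objects.
#' @return named list of \code{gpdc_spectrum} objects.
#' @export
read_gpdc_tsv <- function(path, squared = TRUE, sampling_interval = 2) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  bins <- sort(unique(d$bin_hz))
  k <- max(d$source, d$target)
  out <- lapply(split(d, d$subject), function(ds) {
    vals <- array(0, c(k, k, length(bins)))
    bi <- match(ds$bin_hz, bins)
    vals[cbind(ds$target, ds$source, bi)] <- ds$value
    structure(list(values = vals, bins = bins, squared = squared,
                   sampling_interval = sampling_interval),
              class = "gpdc_spectrum")
  })
  out[unique(d$subject)]
}
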