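#' Construct a centroid peak list
#'
#' A peak list is the reduced representation of one MALDI spot's spectrum:
#' discrete (m/z, intensity) centroid peaks, singly charged by assumption.
#' Peaks are sorted ascending by m/z and duplicate m/z rows are merged keeping
#' the maximum intensity (centroid-export artifacts occasionally emit the same
#' centroid twice).
#'
#' @param mz numeric vector of mass-to-charge values in Da; all > 0.
#' @param intensity numeric vector of signal intensities (arbitrary units,
#'   >= 0), same length as `mz`.
#' @param spot_id identifier of the MALDI spot.
#' @param mode acquisition mode, `"intact"` (linear TOF) or `"digested"`
#'   (reflectron).
#' @return An object of class `peaklist`: a list with elements `spot_id`,
#'   `mode` and `peaks` (a data.frame with columns `mz`, `intensity`).
#' @examples
#' pl <- peaklist(c(1296.5, 1046.2), c(180, 230), spot_id = "s1")
#' pl$peaks   # sorted ascending by m/z
#' @export
peaklist <- function(mz = numeric(), intensity = numeric(),
                     spot_id = "spot", mode = c("intact", "digested")) {
  mode <- match.arg(mode)
  mz <- as.numeric(mz)
  intensity <- as.numeric(intensity)
  if (length(mz) != length(intensity)) {
    stop("'mz' and 'intensity' must have the same length")
  }
  if (anyNA(mz) || anyNA(intensity)) {
    stop("peak list contains missing values")
  }
  if (any(mz <= 0)) stop("all m/z values must be > 0")
  if (any(intensity < 0)) stop("all intensities must be >= 0")
  if (length(mz)) {
    # merge duplicate m/z by maximum intensity, then sort ascending
    if (anyDuplicated(mz)) {
      intensity <- vapply(split(intensity, mz), max, numeric(1))
      mz <- as.numeric(names(intensity))
    }
    o <- order(mz)
    mz <- mz[o]
    intensity <- as.numeric(intensity)[o]
  }
  structure(
    list(spot_id = as.character(spot_id), mode = mode,
         peaks = data.frame(mz = mz, intensity = intensity)),
    class = "peaklist"
  )
}

#' @export
print.peaklist <- function(x, ...) {
  cat(sprintf("<peaklist> spot '%s' (%s mode): %d peaks\n",
              x$spot_id, x$mode, nrow(x$peaks)))
  if (nrow(x$peaks)) {
    cat(sprintf("  m/z range %.2f-%.2f\n",
                min(x$peaks$mz), max(x$peaks$mz)))
  }
  invisible(x)
}

#' @export
length.peaklist <- function(x) nrow(x$peaks)

#' Read a centroid peak list from a comma-delimited file
#'
#' Parses the two-column comma-delimited dialect exported by instrument
#' centroiding software: one `mz,intensity` row per peak, with an optional
#' single header line (auto-detected: a non-numeric first row is treated as a
#' header). Blank lines are skipped; extra columns beyond the first two are
#' ignored with a warning. Duplicate m/z rows are merged keeping the maximum
#' intensity and peaks are sorted ascending.
#'
#' @param path path to the CSV file.
#' @param mode acquisition mode recorded on the returned peak list.
#' @param spot_id spot identifier; defaults to the file name without
#'   extension.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, mode = c("intact", "digested"),
                          spot_id = NULL) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("peak list file not found: ", path)
  if (is.null(spot_id)) {
    spot_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    warning("empty peak list file: ", path)
    return(peaklist(spot_id = spot_id, mode = mode))
  }
  fields <- strsplit(lines, ",", fixed = TRUE)
  first <- suppressWarnings(as.numeric(fields[[1]][1]))
  if (is.na(first)) {  # header line
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (!length(fields)) {
    warning("peak list file contains a header but no data rows: ", path)
    return(peaklist(spot_id = spot_id, mode = mode))
  }
  ncol_seen <- lengths(fields)
  if (any(ncol_seen < 2)) {
    stop(sprintf("cannot parse peak list '%s': line %d has fewer than 2 fields",
                 path, line_no[which(ncol_seen < 2)[1]]))
  }
  if (any(ncol_seen > 2)) {
    warning("ignoring columns beyond the first two in ", path)
  }
  mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  intensity <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  bad <- which(is.na(mz) | is.na(intensity))
  if (length(bad)) {
    stop(sprintf("non-numeric data in peak list '%s' at line %d",
                 path, line_no[bad[1]]))
  }
  if (any(mz <= 0) || any(intensity < 0)) {
    stop(sprintf("invalid peak in '%s': m/z must be > 0 and intensity >= 0",
                 path))
  }
  peaklist(mz, intensity, spot_id = spot_id, mode = mode)
}

#' Write a peak list to a comma-delimited file
#'
#' Writes the `mz,intensity` dialect read by [read_peaklist()], with a header
#' line. Round-tripping a valid peak list through write/read reproduces it
#' exactly.
#'
#' @param pl a [peaklist()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path) {
  stopifnot(inherits(pl, "peaklist"))
  utils::write.table(
    format(pl$peaks, digits = 15, trim = TRUE, scientific = FALSE),
    file = path, sep = ",", row.names = FALSE, col.names = c("mz", "intensity"),
    quote = FALSE
  )
  invisible(path)
}

.manifest_levels <- list(
  label = c("positive", "negative"),
  role  = c("train", "score"),
  mode  = c("intact", "digested")
)

#' Construct and validate a spot manifest
#'
#' The manifest ties peak-list files to their class labels and their role in a
#' trial: the training spreadsheet builds the model, the scoring spreadsheet
#' evaluates it.
#'
#' @param spot_id character vector of unique spot identifiers.
#' @param file character vector of peak-list file paths.
#' @param label class label per spot: `"positive"` or `"negative"`.
#' @param role `"train"` or `"score"`.
#' @param mode `"intact"` or `"digested"`.
#' @param check_files if `TRUE`, every referenced file must exist.
#' @return A data.frame of class `spot_manifest`.
#' @export
spot_manifest <- function(spot_id, file, label, role, mode,
                          check_files = TRUE) {
  m <- data.frame(spot_id = as.character(spot_id), file = as.character(file),
                  label = as.character(label), role = as.character(role),
                  mode = as.character(mode))
  dup <- m$spot_id[duplicated(m$spot_id)]
  if (length(dup)) {
    stop("duplicate spot_id in manifest: ", paste(unique(dup), collapse = ", "))
  }
  for (col in names(.manifest_levels)) {
    bad <- setdiff(unique(m[[col]]), .manifest_levels[[col]])
    if (length(bad)) {
      stop(sprintf("unknown %s token(s) in manifest: %s", col,
                   paste(bad, collapse = ", ")))
    }
  }
  if (check_files) {
    missing <- m$file[!file.exists(m$file)]
    if (length(missing)) {
      stop("manifest references missing file(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  class(m) <- c("spot_manifest", "data.frame")
  m
}

#' Read a spot manifest CSV
#'
#' Expects columns `spot_id,file,label,role,mode`. Relative file paths are
#' resolved against the manifest's directory. Counts per (label, role, mode)
#' are reported as a message.
#'
#' @param path manifest CSV path.
#' @param check_files passed to [spot_manifest()].
#' @return A `spot_manifest`.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("spot_id", "file", "label", "role", "mode")
  missing <- setdiff(required, names(m))
  if (length(missing)) {
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  }
  rel <- !grepl("^(/|[A-Za-z]:)", m$file)
  m$file[rel] <- file.path(dirname(path), m$file[rel])
  out <- spot_manifest(m$spot_id, m$file, m$label, m$role, m$mode,
                       check_files = check_files)
  counts <- as.data.frame(table(label = out$label, role = out$role,
                                mode = out$mode))
  counts <- counts[counts$Freq > 0, ]
  message("manifest: ", nrow(out), " spots; per (label, role, mode): ",
          paste(sprintf("%s/%s/%s=%d", counts$label, counts$role,
                        counts$mode, counts$Freq), collapse = ", "))
  out
}

#' Write a spot manifest CSV
#'
#' @param manifest a `spot_manifest`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "spot_manifest"))
  utils::write.csv(as.data.frame(manifest), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
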