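#' Define a fixed m/z binning scheme
#'
#' A binning scheme divides the mass axis into ordered, non-overlapping
#' ranges, each carrying a bin tolerance (`width`, the full acceptance
#' window) and a bin-center spacing (`spacing`, the delta-M between
#' consecutive centers). Within a range `[start, end)`, bin centers sit at
#' `start + k * spacing` for integer `k >= 0` with `center < end`. The bin
#' label is the center formatted as text: it names a central mass but is used
#' purely as a feature label. The full label set is fixed by the scheme
#' alone, independent of any data, so feature tables built from disjoint
#' data always share identical columns.
#'
#' The guiding principle of bin sizing is that the tolerance must exceed the
#' m/z variability of identical peaks, so identical species always fall in
#' the same bin; [check_jitter()] audits a scheme against a jitter model.
#'
#' @param start,end numeric vectors of range boundaries in Da
#'   (half-open `[start, end)`); ranges must be ascending and
#'   non-overlapping.
#' @param width numeric vector of bin tolerances (full window) in Da.
#' @param spacing numeric vector of center spacings (delta-M) in Da.
#' @return An object of class `bin_scheme`: a data.frame of ranges plus
#'   precomputed centers/labels in attributes.
#' @seealso [intact_scheme()], [digested_scheme()], [assign_bin()]
#' @export
bin_scheme <- function(start, end, width, spacing) {
  spec <- data.frame(start = as.numeric(start), end = as.numeric(end),
                     width = as.numeric(width), spacing = as.numeric(spacing))
  if (!nrow(spec)) stop("a bin scheme needs at least one range")
  if (any(spec$start >= spec$end)) stop("each range must have start < end")
  if (any(spec$width <= 0) || any(spec$spacing <= 0)) {
    stop("width and spacing must be > 0")
  }
  o <- order(spec$start)
  spec <- spec[o, , drop = FALSE]
  if (nrow(spec) > 1 &&
      any(spec$start[-1] < spec$end[-nrow(spec)])) {
    stop("ranges must be non-overlapping and ascending")
  }
  rownames(spec) <- NULL
  centers <- lapply(seq_len(nrow(spec)), function(i) {
    k_max <- ceiling((spec$end[i] - spec$start[i]) / spec$spacing[i]) - 1
    spec$start[i] + (0:k_max) * spec$spacing[i]
  })
  all_centers <- unlist(centers)
  labels <- format(all_centers, trim = TRUE, scientific = FALSE)
  if (anyDuplicated(labels)) stop("bin labels are not unique")
  structure(spec, class = c("bin_scheme", "data.frame"),
            centers = all_centers,
            labels = labels,
            range_index = rep.int(seq_len(nrow(spec)), lengths(centers)))
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %d range(s), %d bins\n", nrow(x),
              length(attr(x, "centers"))))
  print.data.frame(x, ...)
  invisible(x)
}

#' Bin centers and labels of a scheme
#'
#' @param scheme a [bin_scheme()].
#' @return `bin_centers()` the numeric centers; `bin_labels()` their text
#'   labels; `n_bins()` the bin count.
#' @export
bin_centers <- function(scheme) attr(scheme, "centers")

#' @rdname bin_centers
#' @export
bin_labels <- function(scheme) attr(scheme, "labels")

#' @rdname bin_centers
#' @export
n_bins <- function(scheme) length(attr(scheme, "centers"))

#' Default binning scheme for intact (linear-TOF) spectra
#'
#' Five ranges covering 500-20,000 Da with range-specific tolerances
#' (1.25, 2.2, 3.5, 8, 35 Da) and center spacings (1, 2, 5, 10, 50 Da),
#' reflecting the growth of m/z assignment variability with mass in linear
#' mode. 3060 bins in total.
#'
#' @return A [bin_scheme()].
#' @export
intact_scheme <- function() {
  bin_scheme(start = c(500, 1500, 2500, 7000, 12000),
             end = c(1500, 2500, 7000, 12000, 20000),
             width = c(1.25, 2.2, 3.5, 8, 35),
             spacing = c(1, 2, 5, 10, 50))
}

#' Default binning scheme for digested (reflectron) spectra
#'
#' Six ranges covering 200-6999 Da, all with 0.5 Da tolerance and 1 Da
#' center spacing: reflectron m/z assignments for peptides are stable enough
#' for a uniform sub-Da tolerance. 6794 bins in total.
#'
#' @return A [bin_scheme()].
#' @export
digested_scheme <- function() {
  bin_scheme(start = c(200, 1000, 2000, 3000, 4000, 5000),
             end = c(999, 1999, 2999, 3999, 4999, 6999),
             width = rep(0.5, 6),
             spacing = rep(1, 6))
}

#' Default scheme for an acquisition mode
#' @param mode `"intact"` or `"digested"`.
#' @return A [bin_scheme()].
#' @export
default_scheme <- function(mode = c("intact", "digested")) {
  switch(match.arg(mode), intact = intact_scheme(),
         digested = digested_scheme())
}

#' Assign m/z values to bins
#'
#' Each m/z is assigned to the nearest bin center of its containing range,
#' provided the distance does not exceed half the range's tolerance
#' (`width / 2`). An m/z outside every range, or in a range but farther than
#' the tolerance from every center, gets `NA` (the peak is simply not
#' grouped). Exact midpoint ties between two centers break toward the lower
#' center. Vectorized over `mz`.
#'
#' @param mz numeric vector of m/z values (> 0).
#' @param scheme a [bin_scheme()].
#' @param value return `"label"` (default), the numeric `"center"`, or the
#'   global bin `"index"` into `bin_labels(scheme)`.
#' @return Vector of the same length as `mz`; `NA` where unassigned.
#' @examples
#' assign_bin(c(1000.2, 1000.4, 25000), digested_scheme())
#' @export
assign_bin <- function(mz, scheme, value = c("label", "center", "index")) {
  value <- match.arg(value)
  stopifnot(inherits(scheme, "bin_scheme"))
  mz <- as.numeric(mz)
  if (any(mz <= 0, na.rm = TRUE)) stop("m/z values must be > 0")
  spec <- as.data.frame(scheme)
  # locate the containing half-open range, NA if in a gap or outside
  ri <- findInterval(mz, spec$start)
  in_range <- ri >= 1 & !is.na(ri)
  in_range[in_range] <- mz[in_range] < spec$end[ri[in_range]]
  out <- rep(NA_integer_, length(mz))
  idx <- which(in_range)
  if (length(idx)) {
    r <- ri[idx]
    start <- spec$start[r]; spacing <- spec$spacing[r]
    # nearest center, exact midpoints rounded toward the lower center
    k <- ceiling((mz[idx] - start) / spacing - 0.5)
    k_max <- ceiling((spec$end[r] - start) / spacing) - 1
    k <- pmin(pmax(k, 0), k_max)
    center <- start + k * spacing
    ok <- abs(mz[idx] - center) <= spec$width[r] / 2
    # global index = offset of the range's first center + k
    offsets <- cumsum(c(0L, tabulate(attr(scheme, "range_index"),
                                     nbins = nrow(spec))))
    out[idx[ok]] <- offsets[r[ok]] + as.integer(k[ok]) + 1L
  }
  switch(value,
         index = out,
         center = bin_centers(scheme)[out],
         label = bin_labels(scheme)[out])
}

#' Encode one peak list as a feature row
#'
#' Produces one value per bin label of the scheme, in scheme order. Binary
#' encoding marks 1 where at least one peak was assigned to the bin; the
#' intensity encoding carries the aggregated intensity of assigned peaks
#' (maximum by default, robust to split centroids; sum optionally).
#' Unassigned peaks contribute nothing.
#'
#' @param pl a [peaklist()].
#' @param scheme a [bin_scheme()].
#' @param encoding `"binary"` or `"intensity"`.
#' @param aggregate within-bin intensity aggregation, `"max"` (default) or
#'   `"sum"`; ignored for binary encoding.
#' @return Named numeric vector of length `n_bins(scheme)`.
#' @export
encode_peaklist <- function(pl, scheme, encoding = c("binary", "intensity"),
                            aggregate = c("max", "sum")) {
  encoding <- match.arg(encoding)
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(pl, "peaklist"))
  row <- numeric(n_bins(scheme))
  names(row) <- bin_labels(scheme)
  if (nrow(pl$peaks)) {
    idx <- assign_bin(pl$peaks$mz, scheme, value = "index")
    keep <- !is.na(idx)
    if (any(keep)) {
      i <- idx[keep]
      if (encoding == "binary") {
        row[unique(i)] <- 1
      } else {
        v <- pl$peaks$intensity[keep]
        agg <- vapply(split(v, i), if (aggregate == "max") max else sum,
                      numeric(1))
        row[as.integer(names(agg))] <- agg
      }
    }
  }
  row
}

#' Build a spots-by-bins feature table
#'
#' Reads every manifest spot of the requested role, encodes each against the
#' scheme, and stacks the rows in manifest order. Columns are the scheme's
#' bin labels in scheme order, so tables built for the train and score roles
#' of one design are always column-compatible.
#'
#' @param manifest a `spot_manifest` (see [read_manifest()]).
#' @param role `"train"` or `"score"`.
#' @param scheme a [bin_scheme()]; must match the spots' acquisition mode
#'   unless `force = TRUE`.
#' @param encoding `"binary"` or `"intensity"`.
#' @param mode which acquisition mode to select from the manifest; default
#'   takes the single mode present among spots of the role.
#' @param force allow a scheme whose name does not match the mode.
#' @param aggregate passed to [encode_peaklist()].
#' @param peaklists optional named list of in-memory [peaklist()] objects
#'   keyed by `spot_id`; used instead of reading `file` when supplied.
#' @return An object of class `feature_table`: list with `x` (numeric
#'   matrix, rownames = spot ids, colnames = bin labels), `label` (factor
#'   positive/negative per row), `encoding`, `mode`, `role`.
#' @export
build_feature_table <- function(manifest, role = c("train", "score"), scheme,
                                encoding = c("binary", "intensity"),
                                mode = NULL, force = FALSE,
                                aggregate = c("max", "sum"),
                                peaklists = NULL) {
  role <- match.arg(role)
  encoding <- match.arg(encoding)
  stopifnot(inherits(manifest, "spot_manifest"))
  m <- manifest[manifest$role == role, , drop = FALSE]
  if (!is.null(mode)) m <- m[m$mode == mode, , drop = FALSE]
  if (!nrow(m)) stop("no manifest spots with role '", role, "'",
                     if (!is.null(mode)) paste0(" and mode '", mode, "'"))
  modes <- unique(m$mode)
  if (length(modes) > 1) {
    stop("spots of role '", role, "' span several modes (",
         paste(modes, collapse = ", "), "); select one with 'mode ='")
  }
  if (!force && identical(as.data.frame(scheme),
                          as.data.frame(default_scheme(
                            setdiff(c("intact", "digested"), modes))))) {
    stop("scheme is the default for the other acquisition mode than the '",
         modes, "' spots; pass force = TRUE to override")
  }
  if (length(unique(m$label)) < 1) stop("no class labels present")
  rows <- lapply(seq_len(nrow(m)), function(i) {
    pl <- if (!is.null(peaklists)) {
      peaklists[[m$spot_id[i]]]
    } else {
      read_peaklist(m$file[i], mode = m$mode[i], spot_id = m$spot_id[i])
    }
    if (is.null(pl)) stop("no peak list available for spot ", m$spot_id[i])
    r <- encode_peaklist(pl, scheme, encoding = encoding,
                         aggregate = aggregate)
    if (nrow(pl$peaks) && all(r == 0)) {
      warning("spot ", m$spot_id[i],
              ": all peaks fall outside the scheme; all-zero row retained")
    }
    r
  })
  x <- do.call(rbind, rows)
  rownames(x) <- m$spot_id
  structure(list(x = x,
                 label = factor(m$label, levels = c("positive", "negative")),
                 encoding = encoding, mode = modes, role = role),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d spots x %d bins (%s, %s encoding, role %s)\n",
    nrow(x$x), ncol(x$x), x$mode, x$encoding, x$role))
  print(table(x$label))
  invisible(x)
}

#' Write a feature table to CSV
#'
#' First columns are `spot_id` and `label`, then one column per bin label in
#' scheme order.
#'
#' @param ft a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(spot_id = rownames(ft$x), label = as.character(ft$label),
                   check.names = FALSE)
  df <- cbind(df, as.data.frame(ft$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a binning scheme as plain text
#'
#' One line per range: `start,end,width,spacing`, with a header.
#'
#' @param scheme a [bin_scheme()].
#' @param path file path.
#' @return `write_scheme()` returns `path` invisibly; `read_scheme()` a
#'   [bin_scheme()].
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "bin_scheme"))
  utils::write.csv(as.data.frame(scheme), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  df <- utils::read.csv(path)
  bin_scheme(df$start, df$end, df$width, df$spacing)
}

#' Audit a scheme against an m/z jitter model
#'
#' Identical peaks must always fall in one bin, so each range's tolerance
#' should comfortably exceed the m/z assignment variability there. Given a
#' jitter standard deviation proportional to mass (`sigma = jitter_coeff *
#' mass`), this warns for every range whose width is below `4 * sigma` at
#' the range midpoint.
#'
#' @param scheme a [bin_scheme()].
#' @param jitter_coeff Da of m/z standard deviation per Da of mass.
#' @return Invisibly, a data.frame with per-range midpoint sigma and an `ok`
#'   flag; warns when any range fails.
#' @export
check_jitter <- function(scheme, jitter_coeff = 2e-4) {
  stopifnot(inherits(scheme, "bin_scheme"))
  spec <- as.data.frame(scheme)
  mid <- (spec$start + spec$end) / 2
  sigma <- jitter_coeff * mid
  ok <- spec$width >= 4 * sigma
  if (any(!ok)) {
    warning("bin width below 4 * jitter sigma at the midpoint of range(s): ",
            paste(sprintf("[%g, %g)", spec$start[!ok], spec$end[!ok]),
                  collapse = ", "))
  }
  invisible(data.frame(spec, midpoint = mid, jitter_sigma = sigma, ok = ok))
}
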