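#' Raw chromatographic run
#'
#' A `raw_run` holds one sample's profile-mode GC/MS acquisition: an ordered
#' series of MS1 scans (retention time in minutes, m/z values, intensities)
#' plus sample metadata and the oven temperature program. Two internal
#' payloads are supported: a generic per-scan list (as read from mzML/mzXML,
#' where the m/z axis may differ between scans) and a dense grid (a shared
#' integer m/z axis with a scans x m/z intensity matrix, the natural product
#' of the simulator and of unit-mass binning).
#'
#' @param sample_id,group_id character scalars identifying the sample and its
#'   cohort group.
#' @param subset one of `"mother"`, `"child"`, `"room_air"`, `"standard"`.
#' @param rt numeric vector of scan retention times, minutes, strictly
#'   increasing.
#' @param scans list of scans, each `list(mz =, intensity =)` with equal
#'   lengths, m/z ascending, finite non-negative intensities. Exactly one of
#'   `scans` / (`mz`, `intensity`) must be given.
#' @param mz integer-valued m/z axis shared by all scans (grid payload).
#' @param intensity numeric matrix, `length(rt)` rows by `length(mz)` columns.
#' @param ramp_program a [temperature_program()].
#' @return An object of class `raw_run`.
#' @seealso [read_raw_run()], [simulate_run()]
#' @export
raw_run <- function(sample_id, group_id, subset, rt, scans = NULL,
                    mz = NULL, intensity = NULL,
                    ramp_program = temperature_program()) {
  subset <- match.arg(subset, c("mother", "child", "room_air", "standard"))
  rt <- as.numeric(rt)
  if (length(rt) == 0L) stop("empty run: no scans", call. = FALSE)
  if (any(diff(rt) <= 0)) stop("scan retention times must be strictly increasing",
                               call. = FALSE)
  if (is.null(scans) == is.null(intensity))
    stop("give exactly one of 'scans' or 'mz'+'intensity'", call. = FALSE)
  if (!is.null(scans)) {
    if (length(scans) != length(rt)) stop("length(scans) != length(rt)", call. = FALSE)
    for (s in scans) {
      if (length(s$mz) != length(s$intensity))
        stop("scan mz/intensity length mismatch", call. = FALSE)
      if (length(s$mz) && (any(!is.finite(s$mz)) || any(!is.finite(s$intensity))))
        stop("scan values must be finite", call. = FALSE)
      if (length(s$mz) > 1L && any(diff(s$mz) < 0))
        stop("scan m/z values must be ascending", call. = FALSE)
      if (length(s$intensity) && any(s$intensity < 0))
        stop("intensities must be non-negative", call. = FALSE)
    }
  } else {
    intensity <- as.matrix(intensity)
    if (nrow(intensity) != length(rt) || ncol(intensity) != length(mz))
      stop("intensity matrix dimensions do not match rt/mz", call. = FALSE)
    if (any(intensity < 0)) stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 group_id = as.character(group_id),
                 subset = subset,
                 rt = rt, scans = scans,
                 mz = if (is.null(scans)) as.numeric(mz),
                 intensity = if (is.null(scans)) intensity,
                 ramp_program = ramp_program),
            class = "raw_run")
}

#' @export
print.raw_run <- function(x, ...) {
  cat(sprintf("<raw_run> %s (%s/%s): %d scans, %.2f-%.2f min\n",
              x$sample_id, x$group_id, x$subset, length(x$rt),
              min(x$rt), max(x$rt)))
  invisible(x)
}

#' Number of scans in a run
#' @param run a [raw_run()].
#' @return integer scan count.
#' @export
n_scans <- function(run) length(run$rt)

#' Per-scan view of a run
#'
#' Materializes the generic per-scan representation (list of
#' `list(mz, intensity)`) regardless of the internal payload. On grid-backed
#' runs zero-intensity channels are kept, so the scan m/z axis is the grid.
#'
#' @param run a [raw_run()].
#' @return list of scans.
#' @export
run_scans <- function(run) {
  if (!is.null(run$scans)) return(run$scans)
  lapply(seq_along(run$rt), function(i)
    list(mz = run$mz, intensity = run$intensity[i, ]))
}

#' Temperature program of the GC oven
#'
#' Three contiguous ramp windows in run time. The default reproduces a
#' three-ramp program (35 degC held 10 min; 3 degC/min to 121 degC; 20
#' degC/min to 270 degC), i.e. segment boundaries at 10.00 and 38.67 min and
#' a third segment ending at 46.12 min.
#'
#' @param boundaries numeric, the two inner segment boundaries in minutes.
#' @param end numeric, end of the third segment in minutes.
#' @param start numeric, start of acquisition in minutes.
#' @return object of class `temperature_program` with a `segments` matrix
#'   (3 rows, columns `start_rt`, `end_rt`).
#' @export
temperature_program <- function(boundaries = c(10, 38.67), end = 46.12,
                                start = 0) {
  b <- sort(as.numeric(boundaries))
  if (length(b) != 2L || b[1] <= start || b[2] >= end)
    stop("need two inner boundaries between start and end", call. = FALSE)
  segments <- cbind(start_rt = c(start, b[1], b[2]),
                    end_rt   = c(b[1], b[2], end))
  structure(list(segments = segments), class = "temperature_program")
}

## Unit-mass binning: intensity observed at m/z x accrues to bin floor(x + 0.5)
## (round half up), the integer-mass convention of single-quadrupole data.
mz_bin <- function(x) as.integer(floor(x + 0.5))

#' Unit-mass extracted-ion-chromatogram matrix
#'
#' Bins a run onto an integer m/z axis, summing profile intensities that fall
#' in the same unit-mass bin (ties at .5 round up), and returns the dense
#' scans x m/z matrix downstream stages operate on.
#'
#' @param run a [raw_run()].
#' @param mz_range integer length-2, inclusive bounds of the m/z axis; `NULL`
#'   spans the data.
#' @return list with `rt` (minutes), `mz` (integer axis) and `mat`
#'   (intensity matrix, `length(rt)` x `length(mz)`).
#' @export
eic_matrix <- function(run, mz_range = NULL) {
  if (is.null(run$scans) && all(run$mz == round(run$mz))) {
    mz <- as.integer(run$mz)
    mat <- run$intensity
    if (!is.null(mz_range)) {
      keep <- mz >= mz_range[1] & mz <= mz_range[2]
      mz <- mz[keep]; mat <- mat[, keep, drop = FALSE]
    }
    dimnames(mat) <- NULL
    return(list(rt = run$rt, mz = mz, mat = mat))
  }
  scans <- run_scans(run)
  all_mz <- mz_bin(unlist(lapply(scans, `[[`, "mz"), use.names = FALSE))
  all_int <- unlist(lapply(scans, `[[`, "intensity"), use.names = FALSE)
  lens <- vapply(scans, function(s) length(s$mz), integer(1))
  scan_idx <- rep.int(seq_along(scans), lens)
  if (is.null(mz_range)) {
    mz_lo <- min(all_mz); mz_hi <- max(all_mz)
  } else {
    mz_lo <- mz_range[1]; mz_hi <- mz_range[2]
    keep <- all_mz >= mz_lo & all_mz <= mz_hi
    all_mz <- all_mz[keep]; all_int <- all_int[keep]; scan_idx <- scan_idx[keep]
  }
  mz <- seq.int(mz_lo, mz_hi)
  mat <- matrix(0, nrow = length(scans), ncol = length(mz))
  if (length(all_mz)) {
    flat <- (all_mz - mz_lo) * length(scans) + scan_idx  # column-major index
    acc <- rowsum(all_int, group = flat)
    mat[as.integer(rownames(acc))] <- acc[, 1]
  }
  list(rt = run$rt, mz = as.integer(mz), mat = mat)
}

## Rebuild a grid-backed raw_run from an EIC matrix, keeping metadata.
run_from_eics <- function(run, eics) {
  raw_run(run$sample_id, run$group_id, run$subset, rt = eics$rt,
          mz = eics$mz, intensity = eics$mat, ramp_program = run$ramp_program)
}
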