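#' Read a profile-mode GC/MS run from mzML or mzXML
#'
#' Loads all MS1 scans of an open-format chromatogram and returns a
#' [raw_run()]. Retention times are converted to minutes (open formats store
#' seconds). Profile and centroided data are both accepted; downstream
#' unit-mass binning makes the distinction irrelevant for single-quadrupole
#' data.
#'
#' @param path path to an mzML or mzXML file.
#' @param sample_id,group_id,subset sample metadata recorded on the run.
#' @param ramp_program a [temperature_program()]; the default mirrors the
#'   three-ramp acquisition the pipeline targets.
#' @return a [raw_run()] with all MS1 scans in acquisition order.
#' @export
read_raw_run <- function(path, sample_id, group_id, subset,
                         ramp_program = temperature_program()) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  handle <- tryCatch(mzR::openMSfile(path),
                     error = function(e)
                       stopf("cannot read MS data from '%s': %s",
                             path, conditionMessage(e)))
  on.exit(try(mzR::close(handle), silent = TRUE))
  hdr <- tryCatch(mzR::header(handle),
                  error = function(e)
                    stopf("cannot read MS data from '%s': %s",
                          path, conditionMessage(e)))
  if (!nrow(hdr)) stopf("no scans in '%s'", path)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) stopf("no MS1 scans in '%s'", path)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(ms1, function(i) {
    m <- pk[[i]]
    list(mz = as.numeric(m[, 1]), intensity = pmax(as.numeric(m[, 2]), 0))
  })
  rt_min <- hdr$retentionTime[ms1] / 60
  raw_run(sample_id, group_id, subset, rt = rt_min, scans = scans,
          ramp_program = ramp_program)
}

#' Write a run to mzML
#'
#' Serializes a [raw_run()] as mzML (MS1, profile mode); the inverse of
#' [read_raw_run()] up to floating-point storage. Retention times are written
#' in seconds as the format requires.
#'
#' @param run a [raw_run()].
#' @param path output path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  scans <- run_scans(run)
  n <- length(scans)
  pks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  npk <- vapply(pks, nrow, integer(1))
  bp <- vapply(pks, function(m)
    if (nrow(m)) m[which.max(m[, 2]), 1] else 0, numeric(1))
  bpi <- vapply(pks, function(m) if (nrow(m)) max(m[, 2]) else 0, numeric(1))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 0L, peaksCount = npk,
    totIonCurrent = vapply(pks, function(m) sum(m[, 2]), numeric(1)),
    retentionTime = run$rt * 60, basePeakMZ = bp, basePeakIntensity = bpi,
    collisionEnergy = 0, ionisationEnergy = 70,
    lowMZ = vapply(pks, function(m) if (nrow(m)) min(m[, 1]) else 0, numeric(1)),
    highMZ = vapply(pks, function(m) if (nrow(m)) max(m[, 1]) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = FALSE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(vapply(pks, function(m)
      if (nrow(m)) min(m[, 1]) else Inf, numeric(1))),
    scanWindowUpperLimit = max(vapply(pks, function(m)
      if (nrow(m)) max(m[, 1]) else -Inf, numeric(1))),
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}

#' Read an EI spectral library in MSP format
#'
#' Parses the NIST-style MSP text dialect: `Name:` starts an entry, optional
#' `MW:` and `RI:` / `Retention_index:` headers are honoured, unknown headers
#' are ignored, `Num Peaks:` announces the peak list, and peaks are
#' whitespace- or semicolon-separated "m/z intensity" pairs. Spectra are
#' rescaled so the base peak is 1000; entries without an RI carry `NA` rather
#' than 0.
#'
#' @param path path to an MSP text file.
#' @return a `spectral_library`: list with `entries`, each a list with
#'   `name`, `spectrum` (named numeric, names are integer m/z, base peak
#'   1000), `retention_index` (or `NA`) and `molecular_weight` (or `NA`).
#' @export
read_msp_library <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  entries <- list()
  cur <- NULL; peaks_left <- 0L; mzs <- NULL; ints <- NULL
  flush <- function() {
    if (is.null(cur)) return()
    if (peaks_left > 0L)
      stopf("MSP parse error in entry '%s': %d peak(s) missing vs Num Peaks",
            cur$name, peaks_left)
    if (!length(mzs))
      stopf("MSP parse error in entry '%s': no peaks", cur$name)
    spec <- rescale_1000(stats::setNames(ints, as.integer(round(mzs))))
    entries[[length(entries) + 1L]] <<- list(
      name = cur$name, spectrum = spec,
      retention_index = cur$ri, molecular_weight = cur$mw)
    cur <<- NULL; mzs <<- NULL; ints <<- NULL; peaks_left <<- 0L
  }
  for (raw in lines) {
    line <- trimws(raw)
    if (!nzchar(line)) next
    if (grepl("^name\\s*:", line, ignore.case = TRUE)) {
      flush()
      cur <- list(name = trimws(sub("^name\\s*:", "", line, ignore.case = TRUE)),
                  ri = NA_real_, mw = NA_integer_)
      next
    }
    if (is.null(cur)) next  # preamble junk
    if (peaks_left > 0L) {
      toks <- strsplit(gsub("[;,]", " ", line), "\\s+")[[1]]
      toks <- toks[nzchar(toks)]
      vals <- suppressWarnings(as.numeric(toks))
      if (anyNA(vals) || length(vals) %% 2L != 0L)
        stopf("MSP parse error in entry '%s': bad peak line '%s'",
              cur$name, line)
      got <- length(vals) / 2L
      if (got > peaks_left)
        stopf("MSP parse error in entry '%s': more peaks than Num Peaks",
              cur$name)
      idx <- seq_len(got) * 2L
      mzs <- c(mzs, vals[idx - 1L]); ints <- c(ints, vals[idx])
      peaks_left <- peaks_left - got
      next
    }
    if (grepl("^num\\s*peaks\\s*:", line, ignore.case = TRUE)) {
      peaks_left <- as.integer(trimws(sub("^num\\s*peaks\\s*:", "", line,
                                          ignore.case = TRUE)))
      if (is.na(peaks_left) || peaks_left < 1L)
        stopf("MSP parse error in entry '%s': bad Num Peaks", cur$name)
      next
    }
    if (grepl("^(ri|retention_index)\\s*:", line, ignore.case = TRUE)) {
      cur$ri <- suppressWarnings(as.numeric(
        trimws(sub("^(ri|retention_index)\\s*:", "", line, ignore.case = TRUE))))
      next
    }
    if (grepl("^(mw|molweight)\\s*:", line, ignore.case = TRUE)) {
      cur$mw <- suppressWarnings(as.integer(round(as.numeric(
        trimws(sub("^(mw|molweight)\\s*:", "", line, ignore.case = TRUE))))))
      next
    }
    ## any other "Key: value" header line is ignored
  }
  flush()
  if (!length(entries)) stopf("empty MSP library: %s", path)
  structure(list(entries = entries), class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat(sprintf("<spectral_library> %d entries (%d with RI)\n",
              length(x$entries),
              sum(!vapply(x$entries, function(e) is.na(e$retention_index),
                          logical(1)))))
  invisible(x)
}

#' Write an MSP library
#'
#' Inverse of [read_msp_library()]; used to materialize synthetic libraries
#' as fixtures.
#'
#' @param library a `spectral_library`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msp_library <- function(library, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (e in library$entries) {
    writeLines(paste0("Name: ", e$name), con)
    if (!is.null(e$molecular_weight) && !is.na(e$molecular_weight))
      writeLines(paste0("MW: ", e$molecular_weight), con)
    if (!is.null(e$retention_index) && !is.na(e$retention_index))
      writeLines(paste0("RI: ", format(e$retention_index, digits = 10)), con)
    writeLines(paste0("Num Peaks: ", length(e$spectrum)), con)
    mz <- as.integer(names(e$spectrum))
    writeLines(paste(mz, format(unname(e$spectrum), digits = 10),
                     collapse = "; "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write / read the feature matrix as CSV
#'
#' One row per feature group: `feature_id`, `mz`, `rt_median`, then one
#' intensity column per sample. Values survive a round trip to at least six
#' significant digits.
#'
#' @param matrix a `feature_matrix` (see [fill_missing()]).
#' @param path CSV path.
#' @return `path` (write) or a `feature_matrix` (read), invisibly for write.
#' @export
write_feature_matrix <- function(matrix, path) {
  df <- data.frame(feature_id = matrix$features$feature_id,
                   mz = matrix$features$mz,
                   rt_median = matrix$features$rt_median,
                   stringsAsFactors = FALSE)
  vals <- matrix$values
  if (nrow(df)) df <- cbind(df, as.data.frame(vals)) else
    for (s in colnames(vals)) df[[s]] <- numeric(0)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write feature matrix to '%s'", path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- df[, 1:3, drop = FALSE]
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  rownames(vals) <- meta$feature_id
  feature_matrix(
    features = data.frame(feature_id = as.character(meta$feature_id),
                          mz = as.integer(meta$mz),
                          rt_median = as.numeric(meta$rt_median),
                          stringsAsFactors = FALSE),
    values = vals,
    filled = matrix(FALSE, nrow(vals), ncol(vals),
                    dimnames = dimnames(vals)))
}

#' Feature matrix container
#'
#' @param features data.frame with `feature_id`, `mz`, `rt_median` (one row
#'   per cross-sample feature group).
#' @param values numeric matrix, features x samples, no missing cells.
#' @param filled logical matrix marking gap-filled cells.
#' @return object of class `feature_matrix`.
#' @export
feature_matrix <- function(features, values, filled = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(features))
    stop("values rows must match features", call. = FALSE)
  if (is.null(filled))
    filled <- matrix(FALSE, nrow(values), ncol(values), dimnames = dimnames(values))
  structure(list(features = features, values = values, filled = filled),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d features x %d samples (%d filled cells)\n",
              nrow(x$values), ncol(x$values), sum(x$filled)))
  invisible(x)
}
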