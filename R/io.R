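#' Write / read a BOLD time series as TSV
#'
#' Layout: first column \code{time_s}, then one column per region in canonical
#' order; one row per scan.
#'
#' @param bold a \linkS4class{BoldTimeSeries}.
#' @param path TSV file.
#' @return \code{path} (write) or a \linkS4class{BoldTimeSeries} (read).
#' @export
writeTimeseries <- function(bold, path) {
  df <- data.frame(time_s = seq_len(ncol(bold@y)) * bold@tr, t(bold@y),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTimeseries
#' @param regions required region columns.
#' @export
readTimeseries <- function(path, regions = regionNames()) {
  df <- tryCatch(read.delim(path, check.names = FALSE),
                 error = function(e) stop("cannot read time series TSV '",
                                          path, "': ", conditionMessage(e)))
  if (!"time_s" %in% names(df)) stop("missing 'time_s' column in ", path)
  miss <- setdiff(regions, names(df))
  if (length(miss))
    stop("missing region column(s) in ", path, ": ",
         paste(miss, collapse = ", "))
  tt <- df$time_s
  if (length(tt) < 2L) stop("time series must contain at least two scans")
  dts <- diff(tt)
  if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
    stop("non-uniform sampling in ", path)
  y <- t(as.matrix(df[, regions, drop = FALSE]))
  if (!all(is.finite(y))) stop("non-finite values in ", path)
  rownames(y) <- regions
  new("BoldTimeSeries", y = y, tr = dts[1], regions = regions)
}

#' Write / read a task-event table (BIDS-events-like TSV)
#'
#' Columns: onset, duration, trial_type (low / high). Rest periods are
#' implicit gaps.
#'
#' @param epochs data.frame with condition/onset/duration (rest rows are
#'   dropped on write).
#' @param path TSV file.
#' @return \code{path} (write) or an epochs data.frame (read).
#' @export
writeEvents <- function(epochs, path) {
  task <- epochs[epochs$condition %in% c("low", "high"), , drop = FALSE]
  df <- data.frame(onset = task$onset, duration = task$duration,
                   trial_type = task$condition)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEvents
#' @export
readEvents <- function(path) {
  df <- read.delim(path)
  need <- c("onset", "duration", "trial_type")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing event column(s): ", paste(miss, collapse = ", "))
  if (!all(df$trial_type %in% c("low", "high")))
    stop("trial_type must be 'low' or 'high'")
  o <- order(df$onset)
  so <- df[o, ]
  if (nrow(so) > 1L &&
      any(so$onset[-1] < (so$onset + so$duration)[-nrow(so)] - 1e-9))
    stop("overlapping task epochs in ", path)
  data.frame(condition = df$trial_type, onset = df$onset,
             duration = df$duration)
}

#' Write a synthetic cohort bundle
#'
#' Directory layout: \code{design.tsv} (events), \code{sub-XX_bold.tsv} per
#' subject, \code{truth.tsv} (per-subject generative parameters),
#' \code{manifest.json} (groups, seeds, noise SD, design settings).
#'
#' @param cohort a \linkS4class{SyntheticCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeEvents(cohort@design@epochs, file.path(dir, "design.tsv"))
  for (s in cohort@subjects)
    writeTimeseries(s$bold, file.path(dir, paste0(s$id, "_bold.tsv")))
  write.table(cohort@truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(
    subjects = lapply(cohort@subjects, function(s)
      list(id = s$id, group = s$group)),
    master_seed = cohort@masterSeed, noise_sd = cohort@noiseSd,
    tr = cohort@design@tr, microtime_bins = cohort@design@microtimeBins,
    n_scans = cohort@design@nScans)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort bundle written by \code{\link{writeCohort}}
#'
#' @param dir bundle directory.
#' @return List: subjects (id, group, bold), design
#'   (\linkS4class{TaskDesign}), truth (data.frame or NULL), manifest.
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  epochs <- readEvents(file.path(dir, "design.tsv"))
  subjects <- lapply(manifest$subjects, function(s) {
    bold <- readTimeseries(file.path(dir, paste0(s$id, "_bold.tsv")))
    list(id = s$id, group = s$group, bold = bold)
  })
  names(subjects) <- vapply(subjects, function(s) s$id, "")
  n <- subjects[[1]]$bold
  design <- designFromEpochs(epochs, tr = manifest$tr,
                             microtimeBins = manifest$microtime_bins,
                             totalS = manifest$n_scans * manifest$tr)
  truthPath <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truthPath))
    read.delim(truthPath, check.names = FALSE) else NULL
  list(subjects = subjects, design = design, truth = truth,
       manifest = manifest)
}

# content-addressed key for the inversion cache (no digest pkg: serialize to a
# temp file and md5 it)
.contentKey <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(...), tf, version = 2L, compress = FALSE)
  unname(tools::md5sum(tf))
}

#' Write pipeline result objects with a manifest
#'
#' @param objects named list; elements may be data.frame (written as TSV),
#'   matrix with rownames (TSV), or any jsonlite-serializable object (JSON).
#' @param outDir output directory.
#' @param config optional configuration recorded (hashed) in the manifest.
#' @return Manifest list, invisibly (also written to
#'   \code{outDir/manifest.json}).
#' @export
writeResults <- function(objects, outDir, config = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (nm in names(objects)) {
    obj <- objects[[nm]]
    if (is.data.frame(obj)) {
      fn <- paste0(nm, ".tsv")
      write.table(obj, file.path(outDir, fn), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else if (is.matrix(obj)) {
      fn <- paste0(nm, ".tsv")
      write.table(data.frame(id = rownames(obj), obj, check.names = FALSE),
                  file.path(outDir, fn), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    } else {
      fn <- paste0(nm, ".json")
      jsonlite::write_json(obj, file.path(outDir, fn), auto_unbox = TRUE,
                           digits = NA, force = TRUE)
    }
    entries[[nm]] <- fn
  }
  manifest <- list(files = entries,
                   config_hash = if (!is.null(config)) .contentKey(config)
                                 else NULL,
                   package_version =
                     as.character(utils::packageVersion("tcdcm")),
                   r_version = as.character(getRversion()),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
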