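# Delimited-text matrix IO, the checkpoint container, and cohort
# manifests. All numeric output is printed with 17 significant digits so
# write -> read round-trips are bit-exact for doubles.

.fmt17 <- function(x) sprintf("%.17g", x)

#' Read a numeric matrix from delimited text
#'
#' Accepts tab- or comma-separated rectangular numeric text (auto-detected
#' from the first line), with an optional header row (detected when the
#' first row does not parse as numbers). Ragged rows and non-numeric cells
#' are reported with their line number.
#'
#' @param path file path.
#' @return a numeric matrix.
#' @export
readMatrixFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  sep <- if (grepl("\t", lines[1L], fixed = TRUE)) "\t" else ","
  cells <- strsplit(lines, sep, fixed = TRUE)
  firstRow <- 1L
  vals1 <- suppressWarnings(as.numeric(trimws(cells[[1L]])))
  if (anyNA(vals1)) {
    if (length(cells) == 1L)
      stop(sprintf("non-numeric cell at line 1 of %s", path))
    firstRow <- 2L   # header row
  }
  rows <- cells[firstRow:length(cells)]
  widths <- lengths(rows)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf("ragged row at line %d of %s (expected %d cells, got %d)",
                 bad + firstRow - 1L, path, widths[1L], widths[bad]))
  }
  parsed <- lapply(seq_along(rows), function(i) {
    v <- suppressWarnings(as.numeric(trimws(rows[[i]])))
    if (anyNA(v))
      stop(sprintf("non-numeric cell at line %d of %s",
                   i + firstRow - 1L, path))
    v
  })
  do.call(rbind, parsed)
}

#' Write a numeric matrix as delimited text
#'
#' Tab-separated, 17 significant digits, so a subsequent
#' [readMatrixFile()] reproduces the values bit-exactly.
#'
#' @param mat numeric matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMatrixFile <- function(mat, path) {
  if (!is.matrix(mat)) stop("mat must be a matrix")
  txt <- apply(mat, 1L, function(row) paste(.fmt17(row), collapse = "\t"))
  writeLines(txt, path)
  invisible(path)
}

#' Save a propagation network checkpoint
#'
#' A flat JSON container: metadata (region count, layer count, ROI index,
#' residual flag, seed) plus one `W` array (column-major) and one `B`
#' array per layer. Numbers are written with 17 significant digits so the
#' round-trip through [readCheckpoint()] is bit-exact.
#'
#' @param net a [PropagationNetwork-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeCheckpoint <- function(net, path) {
  num <- function(x) paste0("[", paste(.fmt17(as.vector(x)), collapse = ","),
                            "]")
  layerJson <- vapply(net@layers, function(lay)
    sprintf('{"W":%s,"B":%s}', num(lay$W), num(lay$B)), character(1))
  json <- sprintf(paste0(
    '{"format":"hopnet-checkpoint","version":1,',
    '"n_regions":%d,"n_layers":%d,"roi_index":%d,',
    '"residual":%s,"seed":%s,"layers":[%s]}'),
    net@nRegions, net@nLayers, net@roiIndex,
    if (net@residual) "true" else "false",
    if (is.na(net@seed)) "null" else as.character(net@seed),
    paste(layerJson, collapse = ","))
  writeLines(json, path)
  invisible(path)
}

#' Load a propagation network checkpoint
#'
#' @param path a file written by [writeCheckpoint()].
#' @return a [PropagationNetwork-class].
#' @export
readCheckpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "hopnet-checkpoint")
    stop("not a hopnet checkpoint: ", path)
  n <- as.integer(obj$n_regions)
  K <- as.integer(obj$n_layers)
  layers <- lapply(seq_len(K), function(k)
    list(W = matrix(obj$layers$W[[k]], n, n),
         B = as.numeric(obj$layers$B[[k]])))
  new("PropagationNetwork", nRegions = n, nLayers = K,
      roiIndex = as.integer(obj$roi_index),
      residual = isTRUE(obj$residual), layers = layers,
      seed = if (is.null(obj$seed)) NA_integer_ else as.integer(obj$seed))
}

#' Write a cohort to a directory with a manifest
#'
#' One tab-separated matrix file per subject, a targets table
#' (`subject_id`, `target`), and a `manifest.json` recording subject
#' order, relative file paths, region labels, the ROI index and any
#' generator provenance. Subject order in the manifest defines cohort
#' order everywhere.
#'
#' @param cohort a [ConnectomeCohort-class].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  S <- nSubjects(cohort)
  ids <- sprintf("sub-%04d", seq_len(S))
  files <- sprintf("%s_connectome.tsv", ids)
  for (s in seq_len(S))
    writeMatrixFile(connectomes(cohort)[[s]], file.path(dir, files[s]))
  if (length(targets(cohort))) {
    writeLines(c("subject_id\ttarget",
                 sprintf("%s\t%s", ids, .fmt17(targets(cohort)))),
               file.path(dir, "targets.tsv"))
  }
  manifest <- list(
    format = "hopnet-cohort", version = 1L,
    subject_ids = ids, connectome_files = files,
    targets_file = if (length(targets(cohort))) "targets.tsv" else NULL,
    roi_index = roiIndex(cohort),
    region_labels = if (length(cohort@regionLabels)) cohort@regionLabels
                    else NULL,
    n_regions = nRegions(cohort))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a cohort from a manifest directory
#'
#' @param dir directory containing a `manifest.json` written by
#'   [writeCohort()].
#' @return a [ConnectomeCohort-class].
#' @export
readCohort <- function(dir) {
  path <- file.path(dir, "manifest.json")
  if (!file.exists(path)) stop("no manifest.json in ", dir)
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(man$format) || man$format != "hopnet-cohort")
    stop("not a hopnet cohort manifest: ", path)
  mats <- lapply(man$connectome_files,
                 function(f) readMatrixFile(file.path(dir, f)))
  tgt <- numeric(0)
  if (!is.null(man$targets_file)) {
    tab <- utils::read.table(file.path(dir, man$targets_file), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    if (!identical(tab$subject_id, man$subject_ids))
      stop("targets table subject order disagrees with the manifest")
    tgt <- as.numeric(tab$target)
  }
  new("ConnectomeCohort",
      connectomes = mats, targets = tgt,
      roiIndex = as.integer(man$roi_index),
      regionLabels = if (is.null(man$region_labels)) character(0)
                     else as.character(man$region_labels))
}
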