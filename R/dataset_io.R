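## On-disk cohort layout: one directory per subject holding a binary
## triangle surface, one curv file per feature channel, and an annot with
## the ground-truth parcellation — byte-format identical to a real
## FreeSurfer-derived dataset — plus a top-level manifest.

FEATURE_NAMES <- c("area", "curv", "jacobian_white", "sulc", "thickness", "volume")

channelFileNames <- function(nChannels) {
  if (nChannels <= length(FEATURE_NAMES)) FEATURE_NAMES[seq_len(nChannels)]
  else c(FEATURE_NAMES, sprintf("chan%02d", seq_len(nChannels - length(FEATURE_NAMES))))
}

#' Export a cohort to FreeSurfer-format files
#'
#' Writes \code{lh.white}, per-channel \code{lh.<feature>} curv files and
#' \code{lh.labels.annot} under one subdirectory per subject, plus a
#' \code{manifest.tsv} (subject id, vertex count, file checksums via file
#' sizes and value sums).
#'
#' @param subjects list of \linkS4class{CortexSubject}.
#' @param dir output directory (created; must be empty unless
#'   \code{force}).
#' @param force overwrite a non-empty directory.
#' @return the manifest data.frame, invisibly.
#' @export
exportDataset <- function(subjects, dir, force = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop(sprintf("output directory '%s' is not empty (use force)", dir))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(subjects, function(s) {
    sd <- file.path(dir, s@id)
    dir.create(sd, showWarnings = FALSE)
    writeSurface(s@mesh, file.path(sd, "lh.white"))
    chans <- channelFileNames(ncol(s@features))
    for (c in seq_along(chans))
      writeCurv(s@features[, c], file.path(sd, paste0("lh.", chans[c])),
                nFaces = nFaces(s@mesh))
    k <- max(s@labels) + 1L
    writeAnnot(Parcellation(s@labels, defaultLabelTable(k)),
               file.path(sd, "lh.labels.annot"))
    data.frame(id = s@id, nVertices = nVertices(s), nChannels = ncol(s@features),
               nClasses = k, featureSum = sum(s@features),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Import a cohort from FreeSurfer-format files
#'
#' Reads the directory layout written by \code{\link{exportDataset}} (or an
#' equivalently arranged real dataset).
#'
#' @param dir dataset directory with one subdirectory per subject.
#' @return list of \linkS4class{CortexSubject}.
#' @export
importDataset <- function(dir) {
  subdirs <- sort(list.dirs(dir, recursive = FALSE))
  if (length(subdirs) == 0L) stop(sprintf("no subject directories in '%s'", dir))
  lapply(subdirs, function(sd) importSubject(sd))
}

#' @rdname importDataset
#' @param subjectDir one subject's directory.
#' @param requireLabels error when the annot file is missing (training needs
#'   labels; prediction does not).
#' @export
importSubject <- function(subjectDir, requireLabels = TRUE) {
  surf <- file.path(subjectDir, "lh.white")
  if (!file.exists(surf)) stop(sprintf("missing surface file '%s'", surf))
  mesh <- readSurface(surf)
  graph <- buildBrainGraph(mesh)
  curvs <- sort(list.files(subjectDir, pattern = "^lh\\.", full.names = TRUE))
  curvs <- curvs[!basename(curvs) %in% c("lh.white", "lh.labels.annot")]
  known <- paste0("lh.", channelFileNames(length(FEATURE_NAMES)))
  ord <- match(known, basename(curvs))
  curvs <- c(curvs[ord[!is.na(ord)]], curvs[!basename(curvs) %in% known])
  if (length(curvs) == 0L) stop(sprintf("no feature (curv) files in '%s'", subjectDir))
  X <- vapply(curvs, function(p) readCurv(p, expectedN = nVertices(mesh)),
              numeric(nVertices(mesh)))
  annot <- file.path(subjectDir, "lh.labels.annot")
  labels <- if (file.exists(annot)) parcLabels(readAnnot(annot))
  else if (requireLabels) stop(sprintf("missing labels file '%s'", annot))
  else rep(-1L, nVertices(mesh))
  new("CortexSubject", id = basename(subjectDir), mesh = mesh, graph = graph,
      features = unname(X), labels = labels)
}
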