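#' Load a stack of co-registered volumes as a dataset
#'
#' Reads either a directory of NIfTI volumes (`.nii` / `.nii.gz`, one per
#' sample, sample ids taken from file names) or a single `.rds` file holding
#' a named list of arrays. Volumes are cast to double precision; shape
#' homogeneity across samples is enforced, and samples are ordered
#' lexicographically by id so that repeated loads are stable. NIfTI affines
#' are ignored with a warning when non-trivial: the package assumes volumes
#' are already spatially normalized, so only the voxel grid is used.
#'
#' @param path directory of NIfTI files, or an `.rds` file.
#' @param format `"auto"` (by extension), `"nifti_dir"`, or `"rds"`.
#' @param labels optional path to a labels CSV (see [load_labels()]).
#' @return An object of class `volume_dataset`: `ids`, `volumes` (named
#'   list of arrays), optional `labels` (named -1/+1 vector), `provenance`.
#' @export
load_dataset <- function(path, format = c("auto", "nifti_dir", "rds"),
                         labels = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("path not found: %s", path),
                               call. = FALSE)
  if (format == "auto") {
    format <- if (dir.exists(path)) "nifti_dir"
              else if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds"
              else stop("cannot auto-detect format; pass `format`",
                        call. = FALSE)
  }
  if (format == "nifti_dir") {
    files <- list.files(path, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
    if (length(files) == 0L) {
      stop(sprintf("no NIfTI volumes found in %s", path), call. = FALSE)
    }
    ids <- sub("\\.nii(\\.gz)?$", "", basename(files))
    ord <- order(ids)
    files <- files[ord]; ids <- ids[ord]
    volumes <- lapply(files, function(f) {
      img <- RNifti::readNifti(f)
      aff <- tryCatch(RNifti::xform(img), error = function(e) NULL)
      if (!is.null(aff) &&
          !isTRUE(all.equal(unname(aff[seq_len(3), seq_len(3)]),
                            diag(3), tolerance = 1e-6))) {
        warning(sprintf("%s: non-identity affine ignored (volumes assumed pre-registered)",
                        basename(f)), call. = FALSE)
      }
      storage.mode(img) <- "double"
      array(as.numeric(img), dim(img))
    })
  } else {
    volumes <- readRDS(path)
    if (!is.list(volumes)) stop("rds dataset must be a list of arrays",
                                call. = FALSE)
    ids <- names(volumes)
    if (is.null(ids)) ids <- sprintf("sample%03d", seq_along(volumes))
    ord <- order(ids)
    volumes <- lapply(volumes[ord], function(v) {
      storage.mode(v) <- "double"
      v
    })
    ids <- ids[ord]
  }
  if (anyDuplicated(ids)) stop("duplicate sample ids", call. = FALSE)
  names(volumes) <- ids

  shapes <- lapply(volumes, tensor_dim)
  ref <- shapes[[1L]]
  bad <- which(!vapply(shapes, identical, TRUE, ref))
  if (length(bad)) {
    stop(sprintf("heterogeneous volume shapes: %s",
                 paste(sprintf("%s (%s)", ids[c(1L, bad)],
                               vapply(shapes[c(1L, bad)], paste,
                                      "", collapse = "x")),
                       collapse = ", ")), call. = FALSE)
  }
  for (i in seq_along(volumes)) {
    stop_if_not_tensor(volumes[[i]], ids[i])
  }

  lab <- NULL
  if (!is.null(labels)) {
    lab <- load_labels(labels)
    missing_ids <- setdiff(names(lab), ids)
    if (length(missing_ids)) {
      stop(sprintf("labels refer to unknown sample ids: %s",
                   paste(missing_ids, collapse = ", ")), call. = FALSE)
    }
  }
  structure(list(ids = ids, volumes = volumes, labels = lab,
                 provenance = list(path = normalizePath(path),
                                   format = format,
                                   shape = ref)),
            class = "volume_dataset")
}

#' Read a two-column sample-id / label CSV
#'
#' Expects columns `sample_id` and `label` with labels in -1/+1.
#'
#' @param path CSV file path.
#' @return Named numeric vector of -1/+1 labels.
#' @export
load_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels CSV needs columns `sample_id` and `label`", call. = FALSE)
  }
  lab <- as.numeric(df$label)
  if (!all(lab %in% c(-1, 1))) stop("labels must be -1 or +1", call. = FALSE)
  stats::setNames(lab, as.character(df$sample_id))
}

#' Write a dataset to disk as NIfTI volumes plus labels CSV
#'
#' @param samples named list of arrays (names become sample ids) or a
#'   `volume_dataset`.
#' @param dir output directory (created if needed).
#' @param labels optional -1/+1 vector, one per sample.
#' @return The directory path, invisibly.
#' @export
save_dataset <- function(samples, dir, labels = NULL) {
  if (inherits(samples, "volume_dataset")) {
    if (is.null(labels)) labels <- samples$labels
    samples <- samples$volumes
  }
  if (is.null(names(samples))) {
    names(samples) <- sprintf("sample%03d", seq_along(samples))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(samples)) {
    RNifti::writeNifti(RNifti::asNifti(samples[[id]]),
                       file.path(dir, paste0(id, ".nii.gz")))
  }
  if (!is.null(labels) && !all(is.na(labels))) {
    utils::write.csv(data.frame(sample_id = names(samples),
                                label = as.integer(labels)),
                     file.path(dir, "labels.csv"), row.names = FALSE)
  }
  invisible(dir)
}

MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to a single archive
#'
#' Serializes a `gndpca` or `ltc` model together with a format-version tag,
#' so round-trips are lossless and stale archives are rejected explicitly.
#'
#' @param model a `gndpca` or `ltc` object.
#' @param path output file (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (!inherits(model, c("gndpca", "ltc"))) {
    stop("`model` must be a gndpca or ltc object", call. = FALSE)
  }
  saveRDS(list(format_version = MODEL_FORMAT_VERSION,
               model_class = class(model)[1L],
               model = model),
          path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#'
#' @param path archive file path.
#' @return The `gndpca` or `ltc` model.
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("cannot read model archive %s: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || is.null(obj$format_version) || is.null(obj$model)) {
    stop(sprintf("%s is not a model archive", path), call. = FALSE)
  }
  if (obj$format_version != MODEL_FORMAT_VERSION) {
    stop(sprintf("model archive version %s unsupported (expected %d)",
                 obj$format_version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  obj$model
}
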