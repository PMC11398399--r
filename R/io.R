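# Readers and writers for the standard formats the pipeline touches:
# NIfTI-1 volumes (via RNifti), FreeSurfer-style colour lookup tables, and
# cohort CSVs. Convention: 0-based voxel indices, voxel-centre sampling,
# world = affine %*% (i, j, k, 1), RAS orientation assumed on write.

#' Read a NIfTI volume
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @return list with `data` (array; integer dtypes preserved), `affine`
#'   (4x4 voxel-to-world matrix, 0-based indices) and `metadata` (pixel
#'   dimensions and the intent code).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- tryCatch(RNifti::readNifti(path), error = function(e)
    stop("malformed NIfTI file ", path, ": ", conditionMessage(e),
         call. = FALSE))
  hdr <- RNifti::niftiHeader(img)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  list(data = arr, affine = unclass(RNifti::xform(img)),
       metadata = list(pixdim = hdr$pixdim[seq_len(hdr$dim[1] + 1)][-1],
                       intent_code = hdr$intent_code,
                       datatype = hdr$datatype))
}

#' Write a NIfTI volume
#'
#' @param data numeric or integer array (2D-5D). Integer arrays are stored
#'   as int16/int32; 4D probability atlases and vector fields keep float64.
#' @param path output path (.nii or .nii.gz).
#' @param voxel_size mm per voxel (recycled over spatial axes).
#' @param intent optional NIfTI intent code (e.g. 1007 for vector fields).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path, voxel_size = 1, intent = NULL) {
  d <- min(length(dim(data)), 3L)
  vs <- rep(voxel_size, length.out = d)
  img <- RNifti::asNifti(data)
  pd <- RNifti::pixdim(img)
  pd[seq_len(d)] <- vs
  RNifti::pixdim(img) <- pd
  if (!is.null(intent)) img$intent_code <- as.integer(intent)
  dt <- if (is.integer(data)) {
    if (max(abs(range(data))) < 32768) "int16" else "int32"
  } else "double"
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Read a FreeSurfer-style colour lookup table
#'
#' Whitespace-separated rows `id name R G B A`; `#` starts a comment. Extra
#' trailing columns are ignored with a notice.
#'
#' @param path LUT text file.
#' @return data.frame with columns `id, name, R, G, B, A`.
#' @export
read_lut <- function(path) {
  if (!file.exists(path)) stop("cannot read LUT: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- data.frame(id = integer(0), name = character(0), R = integer(0),
                    G = integer(0), B = integer(0), A = integer(0))
  noticed <- FALSE
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    if (length(tok) < 6)
      stop("malformed LUT row (need id name R G B A): '", ln, "'")
    if (length(tok) > 6 && !noticed) {
      message("read_lut: ignoring trailing columns beyond A")
      noticed <- TRUE
    }
    out <- rbind(out, data.frame(id = as.integer(tok[1]), name = tok[2],
                                 R = as.integer(tok[3]),
                                 G = as.integer(tok[4]),
                                 B = as.integer(tok[5]),
                                 A = as.integer(tok[6])))
  }
  if (anyDuplicated(out$id))
    stop("duplicate label id(s) in LUT: ",
         paste(unique(out$id[duplicated(out$id)]), collapse = ", "))
  if (nrow(out) > 0 && (any(out$id < 0) ||
      any(out[, c("R", "G", "B", "A")] < 0) ||
      any(out[, c("R", "G", "B", "A")] > 255)))
    stop("LUT ids must be >= 0 and colour channels in [0, 255]")
  out
}

#' Write a colour lookup table
#' @param lut data.frame as returned by [read_lut()].
#' @param path output path.
#' @export
write_lut <- function(lut, path) {
  writeLines(c("# id name R G B A",
               sprintf("%d %s %d %d %d %d", lut$id, lut$name, lut$R,
                       lut$G, lut$B, lut$A)), path)
  invisible(path)
}

#' Read a cohort table
#'
#' CSV with required columns `subject_id, age_years, sex, icv_mm3` and at
#' least one ROI volume column ending in `_mm3`.
#'
#' @param path CSV file.
#' @return typed data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cannot read cohort: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "age_years", "sex", "icv_mm3")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "))
  rois <- setdiff(grep("_mm3$", names(df), value = TRUE), "icv_mm3")
  if (length(rois) == 0)
    stop("cohort has no ROI volume columns (suffix _mm3)")
  num <- c("age_years", "icv_mm3", rois)
  for (cn in num) df[[cn]] <- as.numeric(df[[cn]])
  df
}

#' Read a tissue-clustering configuration
#'
#' YAML with `classes:` (list of class names) and `map:` (label id ->
#' 1-based class index).
#'
#' @param path YAML file.
#' @return a [tissue_clustering()].
#' @export
read_clustering <- function(path) {
  if (!file.exists(path)) stop("no such clustering config: ", path)
  y <- yaml::read_yaml(path)
  map <- unlist(y$map)
  tissue_clustering(stats::setNames(as.integer(map), names(map)),
                    class_names = unlist(y$classes))
}

#' Serialise a velocity/deformation field as NIfTI
#'
#' Stored as a 4D volume (last axis = vector component) with the NIfTI
#' vector intent code; the field kind is recorded in a JSON sidecar.
#'
#' @param field a [velocity_field()] or [deformation_field()].
#' @param path output path.
#' @export
write_field <- function(field, path) {
  write_volume(field$disp, path, voxel_size = field$voxel_size,
               intent = 1007L)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(kind = class(field)[1],
                            voxel_size = field$voxel_size),
                       side, auto_unbox = TRUE)
  invisible(path)
}

#' Read a serialised field
#' @param path NIfTI path written by [write_field()].
#' @return a [velocity_field()] or [deformation_field()].
#' @export
read_field <- function(path) {
  v <- read_volume(path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  kind <- if (file.exists(side))
    jsonlite::read_json(side)$kind else "deformation_field"
  ctor <- if (kind == "velocity_field") velocity_field else deformation_field
  ctor(v$data, voxel_size = v$metadata$pixdim[1])
}

#' Write a section stack to a directory
#'
#' One 2D NIfTI per section and modality plus a JSON sidecar with section
#' indices, modality tags and ground-truth transform control data.
#'
#' @param stack a [make_section_stack()] stack.
#' @param dir output directory (created).
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(S = stack$S, shape = stack$shape2d,
               slice_indices = stack$slice_indices, sections = list())
  for (s in seq_len(stack$S)) {
    sec <- stack$sections[[s]]
    for (mod in c("M", "A", "B")) {
      write_volume(sec[[mod]],
                   file.path(dir, sprintf("sec%03d_%s.nii.gz", s, mod)))
    }
    meta$sections[[s]] <- list(index = s,
                               modalities = c("M", "A", "B"))
  }
  jsonlite::write_json(meta, file.path(dir, "stack.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
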