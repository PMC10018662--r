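## File formats: NIfTI for volumes/2D images, JSON for polygons, landmarks,
## configs and reports. All lengths are serialized in mm in the documented
## BEV frame; JSON schemas carry a "schema_version" so reports remain
## comparable across releases.

SCHEMA_VERSION <- "1.0"

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

read_json_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
           error = function(e)
             stop("failed to parse JSON at ", path, ": ",
                  conditionMessage(e)))
}

nifti_write <- function(arr, path, spacing) {
  img <- RNifti::asNifti(arr + 0)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

nifti_read <- function(path) {
  img <- RNifti::readNifti(path)
  list(data = as.array(img), spacing = RNifti::pixdim(img))
}

#' Write a structure volume to a case directory
#'
#' Layout: `ct.nii.gz`, `masks/<name>.nii.gz`, `meta.json` (spacing, origin,
#' axes), and `spec.json` when the volume came from a phantom.
#'
#' @param vol a `structure_volume`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case <- function(vol, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  nifti_write(vol$ct, file.path(dir, "ct.nii.gz"), vol$spacing)
  for (nm in names(vol$masks))
    nifti_write(vol$masks[[nm]], file.path(dir, "masks",
                                           paste0(nm, ".nii.gz")),
                vol$spacing)
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       spacing = vol$spacing, origin = vol$origin,
                       axes = vol$axes),
                  file.path(dir, "meta.json"))
  if (!is.null(vol$spec)) write_phantom_spec(vol$spec,
                                             file.path(dir, "spec.json"))
  invisible(dir)
}

#' Read a case directory into a structure volume
#'
#' Expects the [write_case()] layout; any NIfTI spacing (including
#' non-isotropic) is accepted and propagated to all mm computations. When
#' `meta.json` is absent the grid is assumed centered on the isocenter.
#'
#' @param dir case directory.
#' @return A `structure_volume`.
#' @export
read_case <- function(dir) {
  ct_path <- file.path(dir, "ct.nii.gz")
  if (!file.exists(ct_path)) ct_path <- file.path(dir, "ct.nii")
  if (!file.exists(ct_path)) stop("no ct.nii[.gz] under ", dir)
  ct <- nifti_read(ct_path)
  mask_files <- list.files(file.path(dir, "masks"),
                           pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  names(mask_files) <- sub("\\.nii(\\.gz)?$", "", basename(mask_files))
  missing <- setdiff(REQUIRED_STRUCTURES, names(mask_files))
  if (length(missing))
    stop("case at ", dir, " is missing mask(s): ",
         paste(missing, collapse = ", "))
  masks <- lapply(mask_files[REQUIRED_STRUCTURES], function(f)
    nifti_read(f)$data > 0.5)
  meta_path <- file.path(dir, "meta.json")
  d <- dim(ct$data)
  if (file.exists(meta_path)) {
    meta <- read_json_file(meta_path)
    spacing <- as.numeric(meta$spacing)
    origin <- as.numeric(meta$origin)
  } else {
    spacing <- as.numeric(ct$spacing[1:3])
    origin <- -(d - 1) * spacing / 2
  }
  spec <- if (file.exists(file.path(dir, "spec.json")))
    read_phantom_spec(file.path(dir, "spec.json")) else NULL
  for (nm in REQUIRED_STRUCTURES)
    if (!identical(dim(masks[[nm]]), d))
      stop("mask ", nm, " shape differs from ct")
  structure(list(ct = ct$data, masks = masks, spacing = spacing,
                 origin = origin, axes = "x:R->L y:A->P z:I->S",
                 spec = spec),
            class = "structure_volume")
}

#' Write / read a phantom spec as JSON
#' @param spec a [phantom_spec()]; `path` a file path.
#' @return `path` / the `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  x <- unclass(spec)
  x$hu_map <- as.list(x$hu_map)
  x$vertebra_heights <- as.list(x$vertebra_heights)
  write_json_file(c(list(schema_version = SCHEMA_VERSION), x), path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  x <- read_json_file(path)
  x$schema_version <- NULL
  x$hu_map <- unlist(x$hu_map)
  x$vertebra_heights <- unlist(x$vertebra_heights)
  do.call(phantom_spec, x)
}

#' Write / read an aperture config as JSON
#'
#' All fields are optional in the file; absent fields take the package
#' defaults (the initial configuration).
#' @param config an [aperture_config()]; `path` a file path.
#' @return `path` / the `aperture_config`.
#' @export
write_aperture_config <- function(config, path) {
  write_json_file(c(list(schema_version = SCHEMA_VERSION), unclass(config)),
                  path)
}

#' @rdname write_aperture_config
#' @export
read_aperture_config <- function(path) {
  x <- read_json_file(path)
  x$schema_version <- NULL
  known <- names(formals(aperture_config))
  unknown <- setdiff(names(x), known)
  if (length(unknown))
    stop("unknown aperture config field(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(aperture_config, x)
}

#' Write / read a BEV structure set
#'
#' Layout: `frame.json` (grid, gantry, provenance) plus one 2D NIfTI per
#' structure under `masks/`.
#' @param structures a [structure_set_2d()]; `dir` a directory.
#' @return `dir` / the `structure_set_2d`.
#' @export
write_structure_set <- function(structures, dir) {
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(structures$masks))
    nifti_write(structures$masks[[nm]],
                file.path(dir, "masks", paste0(nm, ".nii.gz")),
                structures$spacing)
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       u0 = structures$u[1], v0 = structures$v[1],
                       spacing = structures$spacing,
                       gantry_deg = structures$gantry_deg,
                       provenance = structures$provenance),
                  file.path(dir, "frame.json"))
  invisible(dir)
}

#' @rdname write_structure_set
#' @export
read_structure_set <- function(dir) {
  meta <- read_json_file(file.path(dir, "frame.json"))
  files <- list.files(file.path(dir, "masks"),
                      pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  names(files) <- sub("\\.nii(\\.gz)?$", "", basename(files))
  masks <- lapply(files, function(f) nifti_read(f)$data > 0.5)
  d <- dim(masks[[1]])
  u <- meta$u0 + (seq_len(d[1]) - 1) * meta$spacing[1]
  v <- meta$v0 + (seq_len(d[2]) - 1) * meta$spacing[2]
  geometry <- beam_geometry(gantry_deg = meta$gantry_deg)
  structure_set_2d(masks, u, v, geometry, provenance = meta$provenance)
}

#' Write / read a landmark set as JSON
#' @param landmarks a `landmark_set`; `path` a file path.
#' @return `path` / a `landmark_set` (geometry attributes but not the EB
#'   boundary are restored).
#' @export
write_landmarks <- function(landmarks, path) {
  lm <- unclass(landmarks)
  attributes(lm) <- attributes(lm)[c("dim", "dimnames")]
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       points = apply(lm, 1, function(r)
                         list(u = r[1], v = r[2]), simplify = FALSE),
                       gantry_deg = attr(landmarks, "gantry_deg"),
                       arc = as.data.frame(attr(landmarks, "arc")),
                       config = unclass(attr(landmarks, "config"))),
                  path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  x <- read_json_file(path)
  pts <- t(vapply(x$points, function(p) c(p$u, p$v), numeric(2)))
  rownames(pts) <- names(x$points)
  colnames(pts) <- c("u", "v")
  arc <- as.matrix(x$arc)
  colnames(arc) <- NULL
  cfg <- do.call(aperture_config, x$config)
  structure(pts, class = c("landmark_set", class(pts)),
            config = cfg, arc = arc, eb_boundary = NULL,
            gantry_deg = x$gantry_deg,
            u_anterior = u_anterior_sign(x$gantry_deg))
}

#' Write / read an aperture polygon as JSON
#' @param aperture an `aperture_polygon`; `path` a file path.
#' @return `path` / the `aperture_polygon`.
#' @export
write_aperture <- function(aperture, path) {
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       vertices_mm = as.data.frame(aperture$vertices),
                       gantry_deg = aperture$gantry_deg,
                       provenance = aperture$provenance,
                       config = unclass(aperture$config)),
                  path)
}

#' @rdname write_aperture
#' @export
read_aperture <- function(path) {
  x <- read_json_file(path)
  verts <- unname(as.matrix(x$vertices_mm))
  dimnames(verts) <- list(NULL, c("u", "v"))
  structure(list(vertices = verts, landmarks = NULL,
                 config = do.call(aperture_config, x$config),
                 gantry_deg = x$gantry_deg,
                 u_anterior = u_anterior_sign(x$gantry_deg),
                 provenance = x$provenance),
            class = "aperture_polygon")
}

#' Write / read a QA report as JSON
#' @param report a `qa_report`; `path` a file path.
#' @return `path` / the `qa_report`.
#' @export
write_qa_report <- function(report, path) {
  roi <- if (is.null(report$roi)) NULL
         else list(u = report$roi$u, v = report$roi$v)
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       hd_mm = report$hd, msd_mm = report$msd,
                       roi = roi,
                       thresholds = as.list(report$thresholds),
                       verdict = report$verdict,
                       reason = report$reason,
                       provenance = report$provenance),
                  path)
}

#' @rdname write_qa_report
#' @export
read_qa_report <- function(path) {
  x <- read_json_file(path)
  roi <- if (is.null(x$roi)) NULL
         else structure(list(u = as.numeric(x$roi$u), v = as.numeric(x$roi$v)),
                        class = "evaluation_roi")
  structure(list(hd = x$hd_mm %||% NA_real_, msd = x$msd_mm %||% NA_real_,
                 roi = roi, thresholds = unlist(x$thresholds),
                 verdict = x$verdict, reason = x$reason,
                 provenance = unlist(x$provenance)),
            class = "qa_report")
}

#' Write MLC leaf positions as JSON
#'
#' A DICOM-RT-plan-like export of the per-leaf edge pairs (true DICOM export
#' is out of scope).
#' @param mlc result of [fit_mlc()]; `path` a file path.
#' @return `path`, invisibly.
#' @export
write_mlc <- function(mlc, path) {
  write_json_file(list(schema_version = SCHEMA_VERSION,
                       leaf_width_mm = mlc$leaf_width,
                       leaf_travel_axis = mlc$leaf_travel_axis,
                       jaw_mm = as.list(mlc$jaw),
                       leaves = mlc$leaves),
                  path)
}
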