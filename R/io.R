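#' Read a NIfTI-1 volume
#'
#' Wraps [RNifti::readNifti()]. The returned affine is the NIfTI xform
#' (sform preferred), which maps 0-based voxel indices to world mm — the
#' package-wide convention.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param units unit tag to attach (NIfTI does not carry one), e.g.
#'   `"mm^2/s"`.
#' @return a [scalar_volume()].
#' @export
read_volume <- function(path, units = "") {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI volume: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) > 3L) {
    if (any(d[-(1:3)] > 1L))
      stop(sprintf("expected a 3-D volume but %s has dimensions [%s]",
                   path, paste(d, collapse = ", ")), call. = FALSE)
    d <- d[1:3]
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  scalar_volume(array(as.numeric(img), dim = d), aff, units = units)
}

#' Write a ScalarVolume as NIfTI-1
#'
#' @param vol a [scalar_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_scalar_volume(vol))
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D DWI series plus its FSL gradient table
#'
#' @param path 4-D NIfTI with one 3-D stack per gradient entry.
#' @param bval_path,bvec_path FSL-dialect text files (`bvec` has 3 rows).
#' @return a `DWISeries`: list with `stacks` (4-D array), `affine`,
#'   `gradients` (a `GradientTable`).
#' @export
read_dwi <- function(path, bval_path, bvec_path) {
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI volume: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE))
  d <- dim(img)
  if (length(d) != 4L)
    stop(sprintf("expected a 4-D DWI series but %s has dimensions [%s]",
                 path, paste(d, collapse = ", ")), call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grad <- read_gradient_table(bval_path, bvec_path)
  dwi_series(array(as.numeric(img), dim = d), aff, grad)
}

#' @rdname read_dwi
#' @param stacks 4-D array (x, y, z, gradient).
#' @param affine 4x4 voxel-to-world matrix shared by all stacks.
#' @param gradients a [gradient_table()].
#' @export
dwi_series <- function(stacks, affine, gradients) {
  stopifnot(length(dim(stacks)) == 4L)
  if (dim(stacks)[4] != length(gradients$bvals))
    stop("number of stacks must equal number of gradient entries")
  if (!any(gradients$bvals == 0))
    stop("DWI series must contain at least one b = 0 entry")
  structure(list(stacks = stacks, affine = as.matrix(affine),
                 gradients = gradients), class = "DWISeries")
}

#' Diffusion gradient table
#'
#' @param bvals numeric vector of b-values (s/mm^2), all `>= 0`.
#' @param bvecs n x 3 matrix of gradient directions; nonzero rows must be
#'   unit vectors (renormalised when the norm deviates by at most 1e-3), the
#'   zero vector is allowed for b = 0 entries.
#' @return a `GradientTable` (list with `bvals`, `bvecs`).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as_points(bvecs)
  if (nrow(bvecs) != length(bvals))
    stop("gradient table entry count mismatch: ",
         length(bvals), " b-values vs ", nrow(bvecs), " directions")
  if (any(bvals < 0)) stop("b-values must be >= 0")
  nrm <- sqrt(rowSums(bvecs^2))
  nz <- nrm > 0
  bad <- nz & abs(nrm - 1) > 1e-3
  if (any(bad))
    stop("gradient direction(s) with non-unit norm beyond tolerance: entries ",
         paste(which(bad), collapse = ", "))
  bvecs[nz, ] <- bvecs[nz, , drop = FALSE] / nrm[nz]
  structure(list(bvals = bvals, bvecs = bvecs), class = "GradientTable")
}

#' @rdname gradient_table
#' @param bval_path,bvec_path whitespace-separated FSL-style text files;
#'   `bvec` holds three rows (x, y, z components).
#' @export
read_gradient_table <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  rows <- lapply(readLines(bvec_path), function(l) {
    v <- strsplit(trimws(l), "\\s+")[[1]]
    as.numeric(v[nzchar(v)])
  })
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 3L)
    stop(sprintf("bvec file %s must have 3 rows (found %d)",
                 bvec_path, length(rows)), call. = FALSE)
  if (length(unique(lengths(rows))) != 1L)
    stop("bvec rows have unequal lengths", call. = FALSE)
  bvecs <- t(do.call(rbind, rows))
  if (nrow(bvecs) != length(bvals))
    stop(sprintf("gradient table mismatch: %d b-values but %d directions",
                 length(bvals), nrow(bvecs)), call. = FALSE)
  gradient_table(bvals, bvecs)
}

# ---------------------------------------------------------------------------
# GIFTI (ASCII-encoded DataArrays) — minimal codec built on xml2.

gifti_data_array <- function(values, intent, datatype, dims) {
  fmt <- if (datatype == "NIFTI_TYPE_INT32") "%d" else "%.9g"
  txt <- paste(sprintf(fmt, values), collapse = " ")
  dim_attrs <- stats::setNames(as.list(as.character(dims)),
                               paste0("Dim", seq_along(dims) - 1))
  c(list(Intent = intent, DataType = datatype,
         ArrayIndexingOrder = "RowMajorOrder",
         Dimensionality = as.character(length(dims))),
    dim_attrs,
    list(Encoding = "ASCII", Endian = "LittleEndian", text = txt))
}

write_gifti <- function(arrays, path) {
  doc <- xml2::xml_new_root("GIFTI", Version = "1.0",
                            NumberOfDataArrays = as.character(length(arrays)))
  for (a in arrays) {
    txt <- a$text
    a$text <- NULL
    da <- xml2::xml_add_child(doc, "DataArray")
    for (nm in names(a)) xml2::xml_set_attr(da, nm, a[[nm]])
    xml2::xml_add_child(da, "Data", txt)
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_gifti <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e)
                    stop(sprintf("not a readable GIFTI file: %s", path),
                         call. = FALSE))
  if (xml2::xml_name(doc) != "GIFTI")
    stop(sprintf("not a GIFTI document: %s", path), call. = FALSE)
  das <- xml2::xml_find_all(doc, ".//DataArray")
  lapply(das, function(da) {
    enc <- xml2::xml_attr(da, "Encoding")
    if (!identical(enc, "ASCII"))
      stop(sprintf("unsupported GIFTI encoding '%s' in %s (ASCII expected)",
                   enc, path), call. = FALSE)
    ndim <- as.integer(xml2::xml_attr(da, "Dimensionality"))
    dims <- vapply(seq_len(ndim) - 1L, function(i)
      as.integer(xml2::xml_attr(da, paste0("Dim", i))), integer(1))
    txt <- xml2::xml_text(xml2::xml_find_first(da, ".//Data"))
    vals <- scan(text = txt, quiet = TRUE)
    if (length(vals) != prod(dims))
      stop("GIFTI DataArray size does not match its declared dimensions",
           call. = FALSE)
    list(intent = xml2::xml_attr(da, "Intent"),
         datatype = xml2::xml_attr(da, "DataType"),
         dims = dims, values = vals)
  })
}

# row-major flat vector <-> R matrix
rowmajor_to_matrix <- function(values, dims)
  matrix(values, nrow = dims[1], ncol = dims[2], byrow = TRUE)
matrix_to_rowmajor <- function(m) as.vector(t(m))

#' Read a surface mesh (GIFTI or Wavefront OBJ)
#'
#' GIFTI surfaces need POINTSET and TRIANGLE data arrays (ASCII encoding);
#' OBJ is supported read-only for fixtures. Coordinates are taken to be
#' world mm in the volume frame; no transform is applied.
#'
#' @param path `.gii` / `.surf.gii` or `.obj` file.
#' @return a [triangle_mesh()].
#' @export
read_surface <- function(path) {
  if (grepl("\\.obj$", path, ignore.case = TRUE)) return(read_obj(path))
  das <- read_gifti(path)
  pts <- NULL; tris <- NULL
  for (a in das) {
    if (a$intent == "NIFTI_INTENT_POINTSET")
      pts <- rowmajor_to_matrix(a$values, a$dims)
    if (a$intent == "NIFTI_INTENT_TRIANGLE")
      tris <- rowmajor_to_matrix(a$values, a$dims)
  }
  if (is.null(pts) || is.null(tris))
    stop(sprintf("%s is not a GIFTI surface (needs POINTSET + TRIANGLE)",
                 path), call. = FALSE)
  triangle_mesh(pts, tris + 1L)  # GIFTI indexes vertices from 0
}

#' @rdname read_surface
#' @param mesh a [triangle_mesh()].
#' @return `write_surface()`: `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "TriangleMesh"))
  arrays <- list(
    gifti_data_array(matrix_to_rowmajor(mesh$vertices),
                     "NIFTI_INTENT_POINTSET", "NIFTI_TYPE_FLOAT32",
                     dim(mesh$vertices)),
    gifti_data_array(as.integer(matrix_to_rowmajor(mesh$triangles - 1L)),
                     "NIFTI_INTENT_TRIANGLE", "NIFTI_TYPE_INT32",
                     dim(mesh$triangles)))
  write_gifti(arrays, path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- lines[grepl("^v\\s", lines)]
  flines <- lines[grepl("^f\\s", lines)]
  if (!length(vlines) || !length(flines))
    stop(sprintf("%s is not an OBJ mesh (no v/f records)", path),
         call. = FALSE)
  verts <- t(vapply(strsplit(vlines, "\\s+"), function(x)
    as.numeric(x[2:4]), numeric(3)))
  faces <- lapply(strsplit(flines, "\\s+"), function(x) {
    idx <- x[-1]; idx <- idx[nzchar(idx)]
    as.integer(vapply(strsplit(idx, "/"), `[`, character(1), 1L))
  })
  sizes <- lengths(faces)
  if (any(sizes != 3L))
    stop(sprintf("%s contains non-triangular faces (sizes: %s)", path,
                 paste(sort(unique(sizes)), collapse = ", ")), call. = FALSE)
  triangle_mesh(verts, do.call(rbind, faces))
}

# ---------------------------------------------------------------------------
# Per-vertex data IO

#' Write / read per-vertex data
#'
#' `"csv"` uses the header `vertex_index,value,valid` with 0-based vertex
#' indices and an empty value cell for invalid vertices. `"gifti-func"`
#' writes one FLOAT32 data array with invalid vertices stored as NaN plus a
#' parallel validity array, so the validity mask round-trips.
#'
#' @param map a [vertex_map()].
#' @param path output path.
#' @param format `"gifti-func"` or `"csv"`.
#' @param mesh optional [triangle_mesh()]; when given, the map length is
#'   checked against its vertex count.
#' @return `path` invisibly (`write`), or a [vertex_map()] (`read`).
#' @export
write_vertex_data <- function(map, path, format = c("gifti-func", "csv"),
                              mesh = NULL) {
  stopifnot(inherits(map, "VertexMap"))
  if (length(format) != 1L || !format %in% c("gifti-func", "csv"))
    stop("unknown vertex-data format: ", paste(format, collapse = "/"))
  if (!is.null(mesh) && length(map) != n_vertices(mesh))
    stop(sprintf("map has %d entries but mesh has %d vertices",
                 length(map), n_vertices(mesh)))
  if (format == "csv") {
    val <- ifelse(map$valid, sprintf("%.17g", map$value), "")
    df <- data.frame(vertex_index = seq_along(map$value) - 1L,
                     value = val,
                     valid = ifelse(map$valid, "TRUE", "FALSE"))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  vals <- map$value
  vals[!map$valid] <- NaN
  arrays <- list(
    gifti_data_array(vals, "NIFTI_INTENT_NONE", "NIFTI_TYPE_FLOAT32",
                     length(vals)),
    gifti_data_array(as.integer(map$valid), "NIFTI_INTENT_NONE",
                     "NIFTI_TYPE_INT32", length(vals)))
  write_gifti(arrays, path)
}

#' @rdname write_vertex_data
#' @export
read_vertex_data <- function(path, format = c("gifti-func", "csv")) {
  if (length(format) > 1L)
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv"
              else "gifti-func"
  if (!format %in% c("gifti-func", "csv"))
    stop("unknown vertex-data format: ", format)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = c("integer", "numeric",
                                               "logical"))
    if (!identical(names(df), c("vertex_index", "value", "valid")))
      stop(sprintf("%s lacks the vertex_index,value,valid header", path),
           call. = FALSE)
    ord <- order(df$vertex_index)
    return(vertex_map(df$value[ord], df$valid[ord], method = "file"))
  }
  das <- read_gifti(path)
  vals <- das[[1]]$values
  valid <- if (length(das) >= 2L) as.logical(das[[2]]$values)
           else is.finite(vals)
  vertex_map(vals, valid, method = "file")
}
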