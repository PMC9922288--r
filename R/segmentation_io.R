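# Threshold segmentation of CT volumes to target surfaces, and all file I/O:
# meshes (STL / PLY / VTK legacy / VTP), images (NIfTI, MetaImage), curves
# and metrics (CSV).

# ---- image volume -----------------------------------------------------------

#' Create an image volume
#'
#' @param voxels 3-D numeric array (Hounsfield units).
#' @param spacing mm per axis (length 3).
#' @param origin world coordinate of voxel (1,1,1) center, mm.
#' @return object of class `image_volume`.  World coordinate of 1-based
#'   voxel `(i,j,k)` is `origin + spacing * (c(i,j,k) - 1)` (voxel centers).
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (length(dim(voxels)) != 3) stop("voxels must be a 3-D array")
  if (any(spacing <= 0)) stop("spacing must be positive")
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume: %s voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' Threshold segmentation of the blood pool
#'
#' Contrast-enhanced blood is bright in CT; the blood pool is segmented as
#' all voxels at or above the threshold (default 250 HU), optionally keeping
#' only the largest 26-connected component.
#'
#' @param img an [image_volume()].
#' @param threshold HU threshold (default 250).
#' @param largest_component keep only the largest 26-connected component.
#' @return logical 3-D array (the mask).
#' @export
threshold_blood_pool <- function(img, threshold = 250, largest_component = TRUE) {
  mask <- img$voxels >= threshold
  if (!any(mask)) stop("no blood pool above threshold")
  if (largest_component) {
    lab <- largest_component_26_cpp(as.integer(mask), dim(img$voxels))
    mask <- array(lab == 1L, dim(img$voxels))
  }
  mask
}

#' Extract a surface mesh from a binary mask
#'
#' Isosurface at 0.5 between background and foreground via marching
#' tetrahedra (Kuhn cube subdivision) in world coordinates; the result is
#' closed and oriented outward.
#'
#' @param mask logical/integer 3-D array.
#' @param spacing,origin voxel geometry as in [image_volume()].
#' @return closed [surface_mesh].
#' @export
mask_to_surface <- function(mask, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  mask <- mask != 0
  if (!any(mask)) stop("mask has no foreground voxels")
  res <- marching_tets_cpp(as.integer(mask), dim(mask))
  v <- res$vertices
  v <- sweep(sweep(v, 2, spacing, "*"), 2, origin, "+")
  m <- surface_mesh(v, res$faces)
  if (signed_volume_mm3(m$vertices, m$faces) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

# ---- mesh I/O ---------------------------------------------------------------

mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("stl", "ply", "vtk", "vtp")) {
    stop("unsupported mesh format '", ext,
         "'; supported: .stl, .ply, .vtk (legacy polydata), .vtp")
  }
  ext
}

#' Write a surface mesh
#'
#' Supported formats: ASCII STL (`.stl`, geometry only), ASCII PLY (`.ply`),
#' VTK legacy polydata (`.vtk`) and VTK XML polydata (`.vtp`).  Per-vertex
#' region labels are persisted as an integer attribute `region` in PLY/VTK
#' formats; STL cannot carry labels and is refused when labels are present.
#'
#' @param mesh a [surface_mesh].
#' @param path output path; format from the extension.
#' @param labels optional per-vertex labels (default `mesh$labels`).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, labels = mesh$labels) {
  fmt <- mesh_format(path)
  v <- mesh$vertices; f <- mesh$faces
  num <- function(x) sprintf("%.17g", x)
  con <- file(path, "w")
  on.exit(close(con))
  if (fmt == "stl") {
    if (!is.null(labels)) {
      stop("STL cannot carry per-vertex labels; use PLY or VTK")
    }
    writeLines("solid cardiotrack", con)
    a <- v[f[, 1], , drop = FALSE]
    b <- v[f[, 2], , drop = FALSE]
    cc <- v[f[, 3], , drop = FALSE]
    e1 <- b - a; e2 <- cc - a
    nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                 e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                 e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
    len <- sqrt(rowSums(nrm^2)); len[len == 0] <- 1
    nrm <- nrm / len
    for (i in seq_len(nrow(f))) {
      writeLines(c(
        sprintf("facet normal %s %s %s", num(nrm[i, 1]), num(nrm[i, 2]), num(nrm[i, 3])),
        "  outer loop",
        sprintf("    vertex %s %s %s", num(a[i, 1]), num(a[i, 2]), num(a[i, 3])),
        sprintf("    vertex %s %s %s", num(b[i, 1]), num(b[i, 2]), num(b[i, 3])),
        sprintf("    vertex %s %s %s", num(cc[i, 1]), num(cc[i, 2]), num(cc[i, 3])),
        "  endloop",
        "endfacet"), con)
    }
    writeLines("endsolid cardiotrack", con)
  } else if (fmt == "ply") {
    hdr <- c("ply", "format ascii 1.0", "comment cardiotrack surface",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z")
    if (!is.null(labels)) hdr <- c(hdr, "property int region")
    hdr <- c(hdr, sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices", "end_header")
    writeLines(hdr, con)
    vl <- paste(num(v[, 1]), num(v[, 2]), num(v[, 3]))
    if (!is.null(labels)) vl <- paste(vl, labels)
    writeLines(vl, con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
  } else if (fmt == "vtk") {
    writeLines(c("# vtk DataFile Version 3.0", "cardiotrack surface",
                 "ASCII", "DATASET POLYDATA",
                 sprintf("POINTS %d double", nrow(v))), con)
    writeLines(paste(num(v[, 1]), num(v[, 2]), num(v[, 3])), con)
    writeLines(sprintf("POLYGONS %d %d", nrow(f), 4 * nrow(f)), con)
    writeLines(paste(3, f[, 1] - 1, f[, 2] - 1, f[, 3] - 1), con)
    if (!is.null(labels)) {
      writeLines(c(sprintf("POINT_DATA %d", nrow(v)),
                   "SCALARS region int 1", "LOOKUP_TABLE default"), con)
      writeLines(as.character(labels), con)
    }
  } else { # vtp
    pd <- if (!is.null(labels)) {
      paste0('      <PointData Scalars="region">\n',
             '        <DataArray type="Int32" Name="region" format="ascii">\n',
             "          ", paste(labels, collapse = " "), "\n",
             "        </DataArray>\n      </PointData>\n")
    } else ""
    xml <- paste0(
      '<?xml version="1.0"?>\n',
      '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
      "  <PolyData>\n",
      sprintf('    <Piece NumberOfPoints="%d" NumberOfPolys="%d">\n',
              nrow(v), nrow(f)),
      pd,
      "      <Points>\n",
      '        <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
      paste("         ", apply(v, 1, function(r) paste(num(r), collapse = " ")),
            collapse = "\n"), "\n",
      "        </DataArray>\n      </Points>\n",
      "      <Polys>\n",
      '        <DataArray type="Int32" Name="connectivity" format="ascii">\n',
      "          ", paste(t(f) - 1L, collapse = " "), "\n",
      "        </DataArray>\n",
      '        <DataArray type="Int32" Name="offsets" format="ascii">\n',
      "          ", paste(seq_len(nrow(f)) * 3L, collapse = " "), "\n",
      "        </DataArray>\n      </Polys>\n",
      "    </Piece>\n  </PolyData>\n</VTKFile>\n")
    cat(xml, file = con)
  }
  invisible(path)
}

#' Read a surface mesh
#'
#' Counterpart of [write_mesh()]; see there for formats and label handling.
#'
#' @param path input path.
#' @return a [surface_mesh]; labels attached when present in the file.
#' @export
read_mesh <- function(path) {
  fmt <- mesh_format(path)
  if (fmt == "stl") {
    lines <- readLines(path)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    xyz <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(p) as.numeric(p[2:4])))
    key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
    uk <- !duplicated(key)
    idx <- match(key, key[uk])
    verts <- xyz[uk, , drop = FALSE]
    faces <- matrix(idx, ncol = 3, byrow = TRUE)
    return(surface_mesh(verts, faces))
  }
  if (fmt == "ply") {
    lines <- readLines(path)
    endh <- which(lines == "end_header")[1]
    hdr <- lines[seq_len(endh)]
    nv <- as.integer(sub("element vertex ", "", grep("^element vertex", hdr, value = TRUE)))
    nf <- as.integer(sub("element face ", "", grep("^element face", hdr, value = TRUE)))
    vstart <- grep("^element vertex", hdr)
    fstart <- grep("^element face", hdr)
    vprops <- grep("^property (?!list)", hdr[(vstart + 1):(fstart - 1)],
                   perl = TRUE, value = TRUE)
    pnames <- vapply(strsplit(vprops, "\\s+"), function(p) p[3], "")
    vdat <- do.call(rbind, lapply(strsplit(trimws(lines[endh + seq_len(nv)]), "\\s+"),
                                  as.numeric))
    verts <- vdat[, match(c("x", "y", "z"), pnames), drop = FALSE]
    labels <- if ("region" %in% pnames) as.integer(vdat[, match("region", pnames)]) else NULL
    fdat <- lapply(strsplit(trimws(lines[endh + nv + seq_len(nf)]), "\\s+"), as.integer)
    if (any(vapply(fdat, function(x) x[1], 0L) != 3L)) stop("only triangle faces supported")
    faces <- do.call(rbind, lapply(fdat, function(x) x[2:4] + 1L))
    return(surface_mesh(verts, faces, labels))
  }
  if (fmt == "vtk") {
    lines <- readLines(path)
    ip <- grep("^POINTS", lines)[1]
    nv <- as.integer(strsplit(lines[ip], "\\s+")[[1]][2])
    nums <- as.numeric(scan(text = paste(lines[(ip + 1):length(lines)], collapse = " "),
                            what = "", quiet = TRUE, n = 3 * nv))
    verts <- matrix(nums, ncol = 3, byrow = TRUE)
    ifc <- grep("^POLYGONS", lines)[1]
    nf <- as.integer(strsplit(lines[ifc], "\\s+")[[1]][2])
    fn <- as.integer(scan(text = paste(lines[(ifc + 1):length(lines)], collapse = " "),
                          what = "", quiet = TRUE, n = 4 * nf))
    fm <- matrix(fn, ncol = 4, byrow = TRUE)
    if (any(fm[, 1] != 3L)) stop("only triangle faces supported")
    faces <- fm[, 2:4, drop = FALSE] + 1L
    labels <- NULL
    isc <- grep("^SCALARS region", lines)
    if (length(isc)) {
      labels <- as.integer(scan(text = paste(lines[(isc[1] + 2):length(lines)],
                                             collapse = " "),
                                what = "", quiet = TRUE, n = nv))
    }
    return(surface_mesh(verts, faces, labels))
  }
  # vtp
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  get_arr <- function(xp) {
    nd <- xml2::xml_find_first(piece, xp)
    if (inherits(nd, "xml_missing")) return(NULL)
    as.numeric(strsplit(trimws(xml2::xml_text(nd)), "\\s+")[[1]])
  }
  pts <- get_arr(".//Points/DataArray")
  verts <- matrix(pts, ncol = 3, byrow = TRUE)
  conn <- as.integer(get_arr(".//Polys/DataArray[@Name='connectivity']"))
  offs <- as.integer(get_arr(".//Polys/DataArray[@Name='offsets']"))
  if (any(diff(c(0L, offs)) != 3L)) stop("only triangle faces supported")
  faces <- matrix(conn, ncol = 3, byrow = TRUE) + 1L
  lab <- get_arr(".//PointData/DataArray[@Name='region']")
  surface_mesh(verts, faces, if (is.null(lab)) NULL else as.integer(lab))
}

# ---- image I/O --------------------------------------------------------------

image_format <- function(path) {
  p <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", p)) return("nifti")
  if (grepl("\\.mha$", p)) return("mha")
  if (grepl("\\.mhd$", p)) return("mhd")
  stop("unsupported image format; supported: .nii, .nii.gz, .mha, .mhd")
}

met_types <- c(MET_UCHAR = "integer", MET_CHAR = "integer",
               MET_SHORT = "integer", MET_USHORT = "integer",
               MET_INT = "integer", MET_FLOAT = "double", MET_DOUBLE = "double")
met_sizes <- c(MET_UCHAR = 1L, MET_CHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
               MET_INT = 4L, MET_FLOAT = 4L, MET_DOUBLE = 8L)
met_signed <- c(MET_UCHAR = FALSE, MET_CHAR = TRUE, MET_SHORT = TRUE,
                MET_USHORT = FALSE, MET_INT = TRUE, MET_FLOAT = TRUE,
                MET_DOUBLE = TRUE)

#' Read an image volume (NIfTI or MetaImage)
#'
#' Reads `.nii` / `.nii.gz` (NIfTI-1; datatypes uint8, int16, int32,
#' float32, float64; pixdim spacing, qoffset origin, scl slope/intercept
#' applied; axis-aligned images only) and `.mha` / `.mhd` MetaImage files.
#'
#' @param path input path.
#' @return an [image_volume()].
#' @export
read_image <- function(path) {
  fmt <- image_format(path)
  if (fmt == "nifti") {
    con <- if (grepl("\\.gz$", tolower(path))) gzfile(path, "rb") else file(path, "rb")
    on.exit(close(con))
    hdr <- readBin(con, "raw", 348)
    rd <- function(off, what, n, size) {
      readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
              endian = "little")
    }
    sizeof_hdr <- rd(0, "integer", 1, 4)
    endian <- "little"
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (or unsupported byte order)")
    dim8 <- rd(40, "integer", 8, 2)
    datatype <- rd(70, "integer", 1, 2)
    pixdim <- rd(76, "double", 8, 4)
    vox_offset <- rd(108, "double", 1, 4)
    scl_slope <- rd(112, "double", 1, 4)
    scl_inter <- rd(116, "double", 1, 4)
    qoff <- c(rd(268, "double", 1, 4), rd(272, "double", 1, 4),
              rd(276, "double", 1, 4))
    dims <- dim8[2:4]
    n <- prod(dims)
    skip <- vox_offset - 348
    if (skip > 0) readBin(con, "raw", skip)
    dat <- switch(as.character(datatype),
      "2" = as.numeric(readBin(con, "integer", n, 1, signed = FALSE, endian = endian)),
      "4" = as.numeric(readBin(con, "integer", n, 2, endian = endian)),
      "8" = as.numeric(readBin(con, "integer", n, 4, endian = endian)),
      "16" = readBin(con, "double", n, 4, endian = endian),
      "64" = readBin(con, "double", n, 8, endian = endian),
      stop("unsupported NIfTI datatype ", datatype))
    if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
      dat <- dat * scl_slope + scl_inter
    }
    return(image_volume(array(dat, dims), pixdim[2:4], qoff))
  }
  # MetaImage: text header, optionally followed by local binary data
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, 1)
    if (!length(line)) stop("truncated MetaImage header")
    kv <- strsplit(line, "=")[[1]]
    key <- trimws(kv[1]); val <- trimws(paste(kv[-1], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing)) {
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  } else rep(1, 3)
  origin <- if (!is.null(hdr$Offset)) {
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]])
  } else if (!is.null(hdr$Position)) {
    as.numeric(strsplit(hdr$Position, "\\s+")[[1]])
  } else rep(0, 3)
  type <- hdr$ElementType
  if (!type %in% names(met_types)) stop("unsupported ElementType ", type)
  msb <- identical(hdr$ElementByteOrderMSB, "True") ||
    identical(hdr$BinaryDataByteOrderMSB, "True")
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    dat_con <- con
  } else {
    dat_con <- file(file.path(dirname(path), hdr$ElementDataFile), "rb")
    on.exit(close(dat_con), add = TRUE)
  }
  dat <- readBin(dat_con, met_types[[type]], n, met_sizes[[type]],
                 signed = met_signed[[type]], endian = endian)
  image_volume(array(as.numeric(dat), dims), spacing, origin)
}

#' Write an image volume (NIfTI or MetaImage)
#'
#' Writes `.nii` (NIfTI-1 float32), `.mha` (MetaImage with local binary
#' data, MET_FLOAT) or `.mhd` + `.raw`.
#'
#' @param img an [image_volume()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  fmt <- image_format(path)
  dims <- dim(img$voxels)
  if (fmt == "nifti") {
    if (grepl("\\.gz$", tolower(path))) stop("writing .nii.gz not supported; use .nii")
    con <- file(path, "wb")
    on.exit(close(con))
    hdr <- raw(348)
    put <- function(off, x, size, what = "integer") {
      b <- writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
                    raw(), size = size, endian = "little")
      hdr[(off + 1):(off + length(b))] <<- b
    }
    put(0, 348L, 4)
    put(40, c(3L, dims, 1L, 1L, 1L, 1L), 2)      # dim[8]
    put(70, 16L, 2)                              # datatype float32
    put(72, 32L, 2)                              # bitpix
    put(76, c(1, img$spacing, 0, 0, 0, 0), 4, "double")
    put(108, 352, 4, "double")                   # vox_offset
    put(112, 1, 4, "double")                     # scl_slope
    put(252, 1L, 2)                              # qform_code
    put(268, img$origin[1], 4, "double")
    put(272, img$origin[2], 4, "double")
    put(276, img$origin[3], 4, "double")
    # identity orientation (quaternion b=c=d=0), srow not set
    hdr[345:347] <- as.raw(c(110L, 43L, 49L))    # magic "n+1"
    writeBin(hdr, con)
    writeBin(raw(4), con)                        # pad to vox_offset 352
    writeBin(as.numeric(img$voxels), con, size = 4, endian = "little")
    return(invisible(path))
  }
  header <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
              "BinaryDataByteOrderMSB = False",
              paste("DimSize =", paste(dims, collapse = " ")),
              paste("ElementSpacing =", paste(img$spacing, collapse = " ")),
              paste("Offset =", paste(img$origin, collapse = " ")),
              "ElementType = MET_FLOAT")
  if (fmt == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(header, "ElementDataFile = LOCAL"), con)
    writeBin(as.numeric(img$voxels), con, size = 4, endian = "little")
  } else {
    rawname <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
    con <- file(path, "wb")
    writeLines(c(header, paste("ElementDataFile =", rawname)), con)
    close(con)
    con2 <- file(file.path(dirname(path), rawname), "wb")
    on.exit(close(con2))
    writeBin(as.numeric(img$voxels), con2, size = 4, endian = "little")
  }
  invisible(path)
}

# ---- curve / metrics I/O ----------------------------------------------------

#' Write / read flow and volume curves as CSV
#'
#' Curves are written with a one-line header (`time_s,flow_ml_per_s` or
#' `time_s,volume_ml`) at full floating-point precision, so a re-read
#' reproduces the curve exactly.
#'
#' @param curve a `flow_curve` or `volume_curve`.
#' @param path output path.
#' @return `path` invisibly (write) or a data.frame (read).
#' @export
write_curve <- function(curve, path) {
  is_flow <- "flow" %in% names(curve)
  hdr <- if (is_flow) "time_s,flow_ml_per_s" else "time_s,volume_ml"
  y <- if (is_flow) curve$flow else curve$volume
  writeLines(c(hdr, sprintf("%.17g,%.17g", curve$time, y)), path)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  read.csv(path)
}

#' Write flow metrics as CSV (`metric,value` rows)
#'
#' @param metrics a `flow_metrics` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  vals <- unlist(metrics)
  writeLines(c("metric,value",
               sprintf("%s,%.17g", names(vals), as.numeric(vals))), path)
  invisible(path)
}
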