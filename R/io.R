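fmt_num <- function(x) formatC(x, format = "g", digits = 17)

meta_path <- function(path) paste0(path, ".meta.yaml")

mesh_meta <- function(mesh) {
  list(named_sets = lapply(mesh$named_sets, as.integer),
       element_region = mesh$element_region,
       tri_region = mesh$tri_region,
       tri_thickness = mesh$tri_thickness,
       element_block = mesh$element_block,
       springs = if (nrow(mesh$springs)) lapply(
         seq_len(nrow(mesh$springs)), function(i) {
           s <- mesh$springs[i, ]
           list(node_a = as.integer(s$node_a), node_b = as.integer(s$node_b),
                stiffness = s$stiffness, name = s$name,
                dir = if (is.na(s$dx)) NULL else c(s$dx, s$dy, s$dz))
         }) else list())
}

apply_mesh_meta <- function(mesh, meta) {
  if (is.null(meta)) return(mesh)
  if (!is.null(meta$named_sets))
    mesh$named_sets <- lapply(meta$named_sets, as.integer)
  if (!is.null(meta$element_region))
    mesh$element_region <- as.character(meta$element_region)
  if (!is.null(meta$tri_region))
    mesh$tri_region <- as.character(meta$tri_region)
  if (!is.null(meta$tri_thickness))
    mesh$tri_thickness <- as.double(meta$tri_thickness)
  if (!is.null(meta$element_block))
    mesh$element_block <- as.character(meta$element_block)
  if (length(meta$springs)) {
    mesh$springs <- do.call(rbind, lapply(meta$springs, function(s) {
      data.frame(node_a = s$node_a, node_b = s$node_b, stiffness = s$stiffness,
                 name = s$name,
                 dx = if (is.null(s$dir)) NA_real_ else s$dir[1],
                 dy = if (is.null(s$dir)) NA_real_ else s$dir[2],
                 dz = if (is.null(s$dir)) NA_real_ else s$dir[3])
    }))
  }
  validate_fe_mesh(mesh)
  mesh
}

#' Write a mesh to disk
#'
#' Two ASCII dialects are supported: `vtk_legacy` (unstructured grid; tets as
#' cell type 10, membrane triangles as 5, springs as line cells 3) and
#' `abaqus_inp` (a NODE/ELEMENT/NSET subset with C3D4, S3 and SPRINGA
#' elements).  Data neither dialect carries natively — region labels,
#' membrane thickness, spring stiffness and action lines, and (for VTK)
#' named sets — go to a structured-text sidecar `<path>.meta.yaml` that the
#' reader merges back, so a write/read round trip preserves coordinates
#' exactly, connectivity exactly and named sets verbatim.
#'
#' @param mesh an [fe_mesh].
#' @param path output file path.
#' @param dialect `"vtk_legacy"` or `"abaqus_inp"`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, dialect = c("vtk_legacy", "abaqus_inp")) {
  dialect <- match.arg(dialect)
  if (dialect == "vtk_legacy") write_mesh_vtk(mesh, path) else write_mesh_inp(mesh, path)
  yaml::write_yaml(mesh_meta(mesh), meta_path(path))
  invisible(path)
}

write_mesh_vtk <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(c("# vtk DataFile Version 3.0", "pelvifem unstructured mesh",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(mesh$nodes, 1L, function(p) paste(fmt_num(p), collapse = " ")), con)
  ncell <- nrow(mesh$tets) + nrow(mesh$tris) + nrow(mesh$springs)
  sz <- 5L * nrow(mesh$tets) + 4L * nrow(mesh$tris) + 3L * nrow(mesh$springs)
  writeLines(paste("CELLS", ncell, sz), con)
  if (nrow(mesh$tets))
    writeLines(apply(mesh$tets - 1L, 1L, function(x) paste(c(4L, x), collapse = " ")), con)
  if (nrow(mesh$tris))
    writeLines(apply(mesh$tris - 1L, 1L, function(x) paste(c(3L, x), collapse = " ")), con)
  if (nrow(mesh$springs))
    writeLines(paste(2L, mesh$springs$node_a - 1L, mesh$springs$node_b - 1L), con)
  writeLines(paste("CELL_TYPES", ncell), con)
  writeLines(as.character(c(rep(10L, nrow(mesh$tets)), rep(5L, nrow(mesh$tris)),
                            rep(3L, nrow(mesh$springs)))), con)
}

write_mesh_inp <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("*HEADING", "pelvifem mesh", "*NODE"), con)
  writeLines(paste0(seq_len(nrow(mesh$nodes)), ", ",
                    apply(mesh$nodes, 1L, function(p) paste(fmt_num(p), collapse = ", "))),
             con)
  eid <- 0L
  if (nrow(mesh$tets)) {
    writeLines("*ELEMENT, TYPE=C3D4, ELSET=TETS", con)
    writeLines(paste0(eid + seq_len(nrow(mesh$tets)), ", ",
                      apply(mesh$tets, 1L, paste, collapse = ", ")), con)
    eid <- eid + nrow(mesh$tets)
  }
  if (nrow(mesh$tris)) {
    writeLines("*ELEMENT, TYPE=S3, ELSET=SHELL", con)
    writeLines(paste0(eid + seq_len(nrow(mesh$tris)), ", ",
                      apply(mesh$tris, 1L, paste, collapse = ", ")), con)
    eid <- eid + nrow(mesh$tris)
  }
  if (nrow(mesh$springs)) {
    writeLines("*ELEMENT, TYPE=SPRINGA, ELSET=SPRINGS", con)
    writeLines(paste0(eid + seq_len(nrow(mesh$springs)), ", ",
                      mesh$springs$node_a, ", ", mesh$springs$node_b), con)
  }
  for (nm in names(mesh$named_sets)) {
    writeLines(paste0("*NSET, NSET=", nm), con)
    ids <- mesh$named_sets[[nm]]
    for (chunk in split(ids, ceiling(seq_along(ids) / 12)))
      writeLines(paste(chunk, collapse = ", "), con)
  }
}

#' Read a mesh from disk
#'
#' Counterpart of [write_mesh]; rejects malformed input (unknown cell or
#' element types, wrong node counts) naming the offending record, and
#' rejects inverted tetrahedra listing the offending elements.
#'
#' @param path file path.
#' @param dialect `"vtk_legacy"` or `"abaqus_inp"`.
#' @return an [fe_mesh].
#' @export
read_mesh <- function(path, dialect = c("vtk_legacy", "abaqus_inp")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  mesh <- if (dialect == "vtk_legacy") read_mesh_vtk(path) else read_mesh_inp(path)
  mp <- meta_path(path)
  if (file.exists(mp)) mesh <- apply_mesh_meta(mesh, yaml::read_yaml(mp))
  mesh
}

read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  pts_i <- grep("^POINTS", lines)
  if (length(pts_i) != 1L) stop("not a VTK legacy unstructured grid: ", path)
  n <- as.integer(strsplit(lines[pts_i], "\\s+")[[1]][2])
  coords <- scan(text = lines[(pts_i + 1L):(pts_i + n)], quiet = TRUE)
  nodes <- matrix(coords, ncol = 3L, byrow = TRUE)
  cells_i <- grep("^CELLS", lines)
  ncell <- as.integer(strsplit(lines[cells_i], "\\s+")[[1]][2])
  cell_lines <- lines[(cells_i + 1L):(cells_i + ncell)]
  types_i <- grep("^CELL_TYPES", lines)
  types <- as.integer(unlist(strsplit(trimws(
    lines[(types_i + 1L):(types_i + ncell)]), "\\s+")))
  tets <- list(); tris <- list(); springs <- list()
  for (ci in seq_len(ncell)) {
    rec <- as.integer(strsplit(trimws(cell_lines[ci]), "\\s+")[[1]])
    cnt <- rec[1L]; ids <- rec[-1L] + 1L
    if (length(ids) != cnt)
      stop("malformed VTK cell record ", ci, ": '", cell_lines[ci], "'")
    if (types[ci] == 10L) {
      if (cnt != 4L) stop("VTK cell ", ci, " (type 10) has ", cnt, " nodes, expected 4")
      tets[[length(tets) + 1L]] <- ids
    } else if (types[ci] == 5L) {
      if (cnt != 3L) stop("VTK cell ", ci, " (type 5) has ", cnt, " nodes, expected 3")
      tris[[length(tris) + 1L]] <- ids
    } else if (types[ci] == 3L) {
      springs[[length(springs) + 1L]] <- ids
    } else {
      stop("unsupported VTK cell type ", types[ci], " in record ", ci,
           ": '", cell_lines[ci], "'")
    }
  }
  spr <- if (length(springs)) {
    ab <- do.call(rbind, springs)
    data.frame(node_a = ab[, 1L], node_b = ab[, 2L], stiffness = 1,
               name = "spring", dx = NA_real_, dy = NA_real_, dz = NA_real_)
  } else NULL
  fe_mesh(nodes,
          tets = if (length(tets)) do.call(rbind, tets) else matrix(integer(), ncol = 4L),
          tris = if (length(tris)) do.call(rbind, tris) else NULL,
          tri_thickness = if (length(tris)) 1 else numeric(),
          springs = spr)
}

read_mesh_inp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\*\\*", lines)]
  kw <- grep("^\\*", lines)
  nodes <- NULL; tets <- list(); tris <- list(); springs <- list()
  sets <- list()
  for (s in seq_along(kw)) {
    head_ <- toupper(lines[kw[s]])
    body_ <- lines[seq(kw[s] + 1L,
                       if (s < length(kw)) kw[s + 1L] - 1L else length(lines))]
    body_ <- body_[nzchar(trimws(body_))]
    if (kw[s] + 1L > (if (s < length(kw)) kw[s + 1L] - 1L else length(lines)))
      body_ <- character()
    if (startsWith(head_, "*NODE")) {
      vals <- lapply(strsplit(body_, ","), function(x) as.numeric(trimws(x)))
      ids <- vapply(vals, `[`, double(1), 1L)
      nodes <- matrix(0, max(ids), 3L)
      for (v in vals) nodes[v[1L], ] <- v[2:4]
    } else if (startsWith(head_, "*ELEMENT")) {
      type <- sub(".*TYPE=([A-Z0-9]+).*", "\\1", head_)
      recs <- lapply(strsplit(body_, ","), function(x) as.integer(trimws(x)))
      for (v in recs) {
        conn <- v[-1L]
        if (type == "C3D4") {
          if (length(conn) != 4L)
            stop("element record ", v[1L], " (C3D4) has ", length(conn), " nodes")
          tets[[length(tets) + 1L]] <- conn
        } else if (type == "S3") {
          if (length(conn) != 3L)
            stop("element record ", v[1L], " (S3) has ", length(conn), " nodes")
          tris[[length(tris) + 1L]] <- conn
        } else if (type == "SPRINGA") {
          springs[[length(springs) + 1L]] <- conn
        } else {
          stop("unsupported element type ", type, " at record ", v[1L])
        }
      }
    } else if (startsWith(head_, "*NSET")) {
      nm <- sub(".*NSET=([^,]+).*", "\\1", lines[kw[s]])
      sets[[trimws(nm)]] <- as.integer(unlist(strsplit(paste(body_, collapse = ","), ",")))
    } else if (startsWith(head_, "*HEADING")) {
      # free text, ignore
    } else {
      stop("unsupported keyword: ", lines[kw[s]])
    }
  }
  if (is.null(nodes)) stop("no *NODE block in ", path)
  spr <- if (length(springs)) {
    ab <- do.call(rbind, springs)
    data.frame(node_a = ab[, 1L], node_b = ab[, 2L], stiffness = 1,
               name = "spring", dx = NA_real_, dy = NA_real_, dz = NA_real_)
  } else NULL
  fe_mesh(nodes,
          tets = if (length(tets)) do.call(rbind, tets) else matrix(integer(), ncol = 4L),
          tris = if (length(tris)) do.call(rbind, tris) else NULL,
          tri_thickness = if (length(tris)) 1 else numeric(),
          springs = spr, named_sets = sets)
}

#' Write / read a CT volume as NIfTI-1
#'
#' The affine carries the voxel spacing on its diagonal and the volume-corner
#' origin in its translation column.  Values round-trip exactly (float64
#' payload); spacing and origin round-trip to well under 1e-6 mm.
#'
#' @param vol a [voxel_volume].
#' @param path output `.nii` path.
#' @return `path` invisibly ([write_volume]); a [voxel_volume] ([read_volume]).
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4L] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  dims <- dim(img)
  if (length(dims) != 3L) stop("expected a 3-D volume, got ", length(dims), " dimensions")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(sp <= 0)) stop("non-positive voxel spacing in header")
  aff <- RNifti::xform(img)
  voxel_volume(array(as.double(img), dims), spacing = sp, origin = aff[1:3, 4L])
}

#' Load the passive soft-tissue registry
#'
#' Reads the ligament/muscle table: per-tissue spring stiffness (N/mm per
#' spring), spring count, muscle attachment area (mm^2) and the named origin
#' and insertion patches.  Rows whose stiffness is empty must name the tissue
#' they are co-modelled with (their springs are carried by that parent entry);
#' a non-co-modelled row without stiffness is rejected.  The packaged default
#' (`tissue_registry.csv`) holds the nine ligament and nine muscle entries of
#' the published registry.
#'
#' @param path CSV path; default is the packaged registry.
#' @return a tibble of tissue specifications.
#' @export
load_tissue_table <- function(path = system.file("extdata", "tissue_registry.csv",
                                                 package = "pelvifem")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "class", "k_per_spring", "n_springs", "attachment_area",
            "origin_set", "insertion_set", "co_modeled_with")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("tissue table lacks columns: ", paste(miss, collapse = ", "))
  tab$co_modeled_with[is.na(tab$co_modeled_with)] <- ""
  bad <- is.na(tab$k_per_spring) & tab$co_modeled_with == ""
  if (any(bad))
    stop("tissue rows without stiffness must be co-modelled: ",
         paste(tab$name[bad], collapse = ", "))
  own <- tab$co_modeled_with == ""
  if (any(tab$k_per_spring[own] <= 0, na.rm = TRUE))
    stop("spring stiffness must be > 0")
  if (any(tab$n_springs[own] < 1, na.rm = TRUE))
    stop("spring count must be >= 1")
  tibble::as_tibble(tab)
}

#' Default run configuration
#'
#' All tunables of the integrated pipeline in one structure: material-mapping
#' constants, the constitutive family used for cartilage, spring options,
#' joint penalty stiffness, solver controls and the load schedule (N).
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` list.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    mapping = unclass(mapping_constants()),
    cartilage_family = "mooney_rivlin",
    cartilage_rectified = FALSE,
    tension_only = FALSE,
    joint_penalty = 1e4,
    solver = list(tol = 1e-6, max_iter = 25L, steps = 5L),
    loads = list(magnitudes = c(50, 150, 250, 350, 450, 550),
                 direction = c(0, -1, 0)))
  over <- list(...)
  cfg[names(over)] <- over
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  m <- cfg$loads$magnitudes
  if (length(m) && (any(m <= 0) || any(diff(m) <= 0)))
    stop("load schedule must be strictly increasing and positive")
  if (cfg$solver$tol <= 0) stop("solver tolerance must be > 0")
  if (!cfg$cartilage_family %in% c("mooney_rivlin", "cartilage"))
    stop("cartilage_family must be 'mooney_rivlin' or 'cartilage'")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys override [default_run_config].
#' @return a `run_config` list.
#' @export
read_run_config <- function(path) {
  over <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    } else cfg[[nm]] <- over[[nm]]
  }
  validate_run_config(cfg)
}

#' Write an experiment report to JSON
#'
#' @param report a list or `experiment_report` as produced by the experiment
#'   driver; tibbles are serialised as data-frame records.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", force = TRUE)
  invisible(path)
}
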