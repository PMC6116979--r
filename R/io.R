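#' Write element fields to a VTK legacy unstructured grid
#'
#' Serialises element centres as VTK vertex cells with one `CELL_DATA`
#' scalar array per field column, in the ASCII legacy dialect (readable by
#' ParaView and dependency-free to parse).  Values are written with 17
#' significant digits so that a write/read round trip preserves doubles
#' exactly.  Character columns (e.g. the region label) are encoded as
#' integer codes with the level set stored in the array name
#' (`name:lev1|lev2|...`).
#'
#' @param centres n x 3 matrix of element centres
#' @param fields data.frame of per-element fields
#' @param path output file
#' @param title dataset title line
#' @return `path`, invisibly
#' @export
write_mesh_vtk <- function(centres, fields, path, title = "spineadapt fields") {
  centres <- as.matrix(centres)
  n <- nrow(centres)
  stopifnot(nrow(fields) == n)
  num <- function(x) formatC(x, digits = 17, format = "g")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               paste("POINTS", n, "double")), con)
  writeLines(apply(centres, 1, function(p) paste(num(p), collapse = " ")),
             con)
  writeLines(paste("CELLS", n, 2 * n), con)
  writeLines(paste(1, seq_len(n) - 1), con)
  writeLines(paste("CELL_TYPES", n), con)
  writeLines(rep("1", n), con)
  writeLines(paste("CELL_DATA", n), con)
  for (nm in names(fields)) {
    col <- fields[[nm]]
    if (is.character(col) || is.factor(col)) {
      col <- as.factor(col)
      name <- paste0(nm, ":", paste(levels(col), collapse = "|"))
      writeLines(c(paste("SCALARS", name, "int", 1),
                   "LOOKUP_TABLE default"), con)
      writeLines(as.character(as.integer(col)), con)
    } else {
      writeLines(c(paste("SCALARS", nm, "double", 1),
                   "LOOKUP_TABLE default"), con)
      writeLines(num(col), con)
    }
  }
  invisible(path)
}

#' Read element fields from a VTK legacy unstructured grid
#'
#' Parses the dialect written by [write_mesh_vtk()] (vertex cells plus
#' named `CELL_DATA` scalar arrays).  Unknown array names are preserved as
#' columns.  Malformed files raise an error naming the offending line.
#'
#' @param path file to read
#' @return list with `centres` (matrix) and `fields` (data.frame)
#' @export
read_mesh_vtk <- function(path) {
  lines <- readLines(path)
  fail <- function(i, why) {
    stop("VTK parse error at line ", i, ": ", why, call. = FALSE)
  }
  if (length(lines) < 1 || !grepl("^# vtk DataFile", lines[1])) {
    fail(1, "missing VTK header")
  }
  if (length(lines) < 4 || !grepl("^DATASET UNSTRUCTURED_GRID", lines[4])) {
    fail(4, "expected DATASET UNSTRUCTURED_GRID")
  }
  if (length(lines) < 5) fail(5, "truncated file")
  i <- 5
  m <- regmatches(lines[i], regexec("^POINTS ([0-9]+) ", lines[i]))[[1]]
  if (length(m) < 2) fail(i, "expected POINTS declaration")
  n <- as.integer(m[2])
  pts <- lines[(i + 1):(i + n)]
  centres <- t(vapply(seq_along(pts), function(j) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(pts[j]), "\\s+")[[1]]))
    if (length(v) != 3 || anyNA(v)) fail(i + j, "bad point coordinates")
    v
  }, numeric(3)))
  colnames(centres) <- c("x", "y", "z")
  i <- i + n + 1
  if (!grepl("^CELLS ", lines[i])) fail(i, "expected CELLS")
  i <- i + n + 1
  if (!grepl("^CELL_TYPES ", lines[i])) fail(i, "expected CELL_TYPES")
  i <- i + n + 1
  fields <- list()
  if (i <= length(lines) && grepl("^CELL_DATA ", lines[i])) {
    i <- i + 1
    while (i <= length(lines) && grepl("^SCALARS ", lines[i])) {
      hdr <- strsplit(lines[i], "\\s+")[[1]]
      if (length(hdr) < 3) fail(i, "bad SCALARS declaration")
      name <- hdr[2]; type <- hdr[3]
      if (!grepl("^LOOKUP_TABLE", lines[i + 1])) {
        fail(i + 1, "expected LOOKUP_TABLE")
      }
      vals <- lines[(i + 2):(i + 1 + n)]
      x <- suppressWarnings(as.numeric(vals))
      if (anyNA(x)) fail(i + 1 + which(is.na(x))[1], "non-numeric value")
      if (grepl(":", name)) {
        parts <- strsplit(name, ":")[[1]]
        levs <- strsplit(parts[2], "\\|")[[1]]
        fields[[parts[1]]] <- levs[as.integer(x)]
      } else if (type == "int") {
        fields[[name]] <- as.integer(x)
      } else {
        fields[[name]] <- x
      }
      i <- i + 2 + n
    }
  }
  list(centres = centres,
       fields = as.data.frame(fields, stringsAsFactors = FALSE))
}

#' Write/read element fields as CSV (fallback format)
#'
#' Plain CSV with an `element_id` column followed by one column per field;
#' doubles survive a round trip exactly (17 significant digits).
#'
#' @param fields data.frame of per-element fields
#' @param path file path
#' @return `path` invisibly (write); data.frame without the id column
#'   (read)
#' @export
write_fields_csv <- function(fields, path) {
  out <- cbind(element_id = seq_len(nrow(fields)), fields)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x)
    formatC(x, digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fields_csv
#' @export
read_fields_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"element_id" %in% names(df)) {
    stop("CSV field file must contain an element_id column")
  }
  df$element_id <- NULL
  df
}

#' Run manifest
#'
#' JSON manifest that pins a simulation run: configuration hash, seed,
#' schedule, package version and snapshot index.  Two runs with identical
#' manifests produce identical outputs.
#'
#' @param fit a `spine_adapt` object
#' @param seed the seed used for the fixtures
#' @param path output JSON path
#' @return the manifest list, invisibly
#' @export
write_manifest <- function(fit, seed, path) {
  cfg_file <- tempfile(fileext = ".yaml")
  on.exit(unlink(cfg_file))
  yaml::write_yaml(fit$config, cfg_file)
  manifest <- list(
    package = "spineadapt",
    version = as.character(utils::packageVersion("spineadapt")),
    seed = seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    schedule = list(windows = fit$schedule$windows,
                    micro_dt = fit$schedule$micro_dt,
                    order = fit$schedule$order),
    load_change = as.list(fit$load_change),
    snapshots = vapply(fit$snapshots, function(s) s$day, numeric(1))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(manifest)
}
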