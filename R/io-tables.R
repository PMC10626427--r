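#' Read a STAR particle table
#'
#' Parses the first `data_` block containing a `loop_` with named columns
#' (`_rlnCoordinateX` style tags; the leading underscore and any `#N` column
#' index are stripped, and an `rln` prefix is dropped). Values that parse as
#' numbers become numeric columns; comment lines (`#`) are ignored.
#'
#' @param path Path to a STAR file.
#' @return A data.frame, one row per particle.
#' @export
read_star <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[!startsWith(lines, "#")]
  li <- which(lines == "loop_")
  if (length(li) == 0L) stop("no loop_ block found in STAR file")
  i <- li[1] + 1L
  cols <- character()
  while (i <= length(lines) && startsWith(lines[i], "_")) {
    tag <- sub("^_", "", strsplit(lines[i], "[[:space:]]+")[[1]][1])
    tag <- sub("^rln", "", tag)
    cols <- c(cols, tag)
    i <- i + 1L
  }
  if (length(cols) == 0L) stop("loop_ block declares no columns")
  body <- lines[i:length(lines)]
  body <- body[nzchar(body)]
  stop_at <- which(startsWith(body, "data_") | body == "loop_")
  if (length(stop_at)) body <- body[seq_len(stop_at[1] - 1L)]
  if (length(body) == 0L) return(stats::setNames(as.data.frame(
    matrix(nrow = 0, ncol = length(cols))), cols))
  fields <- strsplit(body, "[[:space:]]+")
  bad <- which(lengths(fields) != length(cols))
  if (length(bad))
    stop(sprintf("STAR row %d has %d fields, expected %d",
                 bad[1], length(fields[[bad[1]]]), length(cols)))
  out <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(out) <- cols
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(v)) out[[j]] <- v
  }
  out
}

#' Write a data.frame as a STAR particle table
#'
#' @param df A data.frame.
#' @param path Output path.
#' @param block Name of the data block (default `particles`).
#' @return `path`, invisibly.
#' @export
write_star <- function(df, path, block = "particles") {
  stopifnot(is.data.frame(df))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("data_%s", block), "", "loop_"), con)
  writeLines(sprintf("_%s #%d", names(df), seq_along(df)), con)
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) format(col, trim = TRUE, digits = 10, scientific = FALSE)
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(apply(fmt, 1L, paste, collapse = "  "), con)
  invisible(path)
}

.particle_required <- c("x", "y", "z", "rot", "tilt", "psi",
                        "class_label", "cc", "filament_id")

#' Read a particle table (STAR or TSV)
#'
#' Dispatches on file extension (`.star` vs anything else, read as
#' tab-separated with a header row). The table must carry coordinates
#' (`x`, `y`, `z`), Euler angles (`rot`, `tilt`, `psi`), `class_label`,
#' `cc` and `filament_id`; extra columns pass through untouched.
#'
#' @param path Input path.
#' @return A data.frame.
#' @export
read_particles <- function(path) {
  df <- if (grepl("\\.star$", path, ignore.case = TRUE)) read_star(path)
        else utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  missing_cols <- setdiff(.particle_required, names(df))
  if (length(missing_cols))
    stop("particle table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write a particle table (STAR or TSV)
#'
#' @param df A data.frame.
#' @param path Output path; `.star` selects STAR format, otherwise TSV.
#' @return `path`, invisibly.
#' @export
write_particles <- function(df, path) {
  if (grepl("\\.star$", path, ignore.case = TRUE)) write_star(df, path)
  else utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read filament trace points
#'
#' Plain-text trace files: one point per line, `filament_id x y z` in nm,
#' `#` comments tolerated.
#'
#' @param path Input path.
#' @param kind Trace kind to attach to every filament.
#' @return Named list of [filament_trace()] objects.
#' @export
read_trace_points <- function(path, kind = "luminal") {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("filament_id", "x", "y", "z"),
                          stringsAsFactors = FALSE)
  ids <- unique(df$filament_id)
  out <- lapply(ids, function(id) {
    p <- as.matrix(df[df$filament_id == id, c("x", "y", "z")])
    filament_trace(p, id = id, kind = kind)
  })
  stats::setNames(out, as.character(ids))
}

#' Write filament traces as a plain-text point file
#'
#' @param traces List of [filament_trace()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_points <- function(traces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# filament_id x_nm y_nm z_nm", con)
  for (tr in traces) {
    p <- tr$points
    writeLines(sprintf("%s %.6g %.6g %.6g", tr$id, p[, 1], p[, 2], p[, 3]), con)
  }
  invisible(path)
}

#' Read a plain-text key=value configuration file
#'
#' Unknown keys are rejected so that typos fail loudly. Values parse to
#' numeric where possible.
#'
#' @param path Input path.
#' @param known Character vector of allowed keys.
#' @return Named list.
#' @export
read_config <- function(path, known = c(
    "keep_fraction", "f_major", "f_minor", "cc_min", "cc_stat",
    "lumen_radius_nm", "mask_diameter_nm", "fft_box", "bin_to",
    "twist_min", "twist_max", "rise_min", "rise_max", "outer_diameter_ang",
    "wedge_halfangle", "noise_sigma", "apix", "seed")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  if (any(lengths(kv) != 2L)) stop("config lines must be key=value")
  keys <- trimws(vapply(kv, `[`, "", 1L))
  vals <- trimws(vapply(kv, `[`, "", 2L))
  unknown <- setdiff(keys, known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  out <- lapply(vals, function(v) {
    n <- suppressWarnings(as.numeric(v)); if (is.na(n)) v else n
  })
  stats::setNames(out, keys)
}
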