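#' Read a colvars-style trajectory table
#'
#' Parses the plain-text columnar dialect used for collective-variable time
#' series: lines starting with `#` are headers or comments, the first header
#' names the columns (first column the time), and data rows are
#' whitespace-separated numbers.  Repeated identical header lines (from
#' restarts) are tolerated; a mid-file header naming different columns is an
#' error.
#'
#' @param path file path.
#' @return data frame with the declared column names; attribute `source`
#'   records the path.
#' @export
read_colvars <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_hdr <- startsWith(trimws(lines), "#")
  hdrs <- trimws(sub("^\\s*#", "", lines[is_hdr]))
  hdrs <- hdrs[nzchar(hdrs) & !startsWith(hdrs, "!")]
  if (!length(hdrs)) stop("no header line naming columns in ", path)
  cols <- strsplit(hdrs[1], "\\s+")[[1]]
  for (h in hdrs[-1]) {
    hc <- strsplit(h, "\\s+")[[1]]
    if (length(hc) == length(cols) && !all(hc == cols))
      stop("inconsistent repeated header in ", path)
  }
  data_lines <- lines[!is_hdr]
  if (!length(data_lines)) stop("no data rows in ", path)
  fields <- strsplit(trimws(data_lines), "\\s+")
  widths <- lengths(fields)
  if (any(widths != length(cols))) {
    bad <- which(widths != length(cols))[1]
    stop("row ", bad, " of ", path, " has ", widths[bad],
         " fields; header declares ", length(cols))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = length(cols), byrow = TRUE)
  if (anyNA(m)) stop("non-numeric field in ", path)
  df <- as.data.frame(m)
  names(df) <- cols
  tt <- df[[1]]
  if (length(tt) > 1L && any(diff(tt) <= 0)) {
    bad <- which(diff(tt) <= 0)[1] + 1L
    stop("times not strictly increasing in ", path, " at t = ", tt[bad])
  }
  attr(df, "source") <- path
  df
}

# provenance comment lines written at the top of every output file
provenance_lines <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("pathpmf"))
  c(paste0("#! pathpmf ", v),
    if (!is.null(seed)) paste0("#! seed ", seed))
}

#' Write a colvars-style trajectory table
#'
#' @param df data frame of numeric columns (first column the time).
#' @param path output path.
#' @param seed optional seed recorded in the provenance header.
#' @return `path`, invisibly.
#' @export
write_colvars <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  writeLines(paste0("# ", paste(names(df), collapse = " ")), con)
  body <- apply(as.matrix(df), 1, function(r)
    paste(format(r, digits = 17, trim = TRUE, scientific = TRUE),
          collapse = " "))
  writeLines(body, con)
  invisible(path)
}

#' Export a sample set as a colvars-style data frame
#'
#' @param samples a [sample_set()].
#' @param names optional CV component names.
#' @return data frame: time, components, window, replica.
#' @export
samples_to_table <- function(samples, names = NULL) {
  stopifnot(inherits(samples, "sample_set"))
  if (is.null(names)) names <- paste0("cv", seq_len(samples$d))
  df <- data.frame(time = samples$time)
  for (j in seq_len(samples$d)) df[[names[j]]] <- samples$coords[, j]
  df$window <- samples$window
  df$replica <- samples$replica
  df
}

#' Write a string path to JSON
#'
#' Round-trips losslessly through [read_string_path()].
#'
#' @param path a [string_path()].
#' @param file output JSON path.
#' @param seed optional seed recorded in the provenance field.
#' @return `file`, invisibly.
#' @export
write_string_path <- function(path, file, seed = NULL) {
  stopifnot(inherits(path, "string_path"))
  obj <- list(provenance = paste0("pathpmf ",
                                  as.character(utils::packageVersion("pathpmf"))),
              seed = seed,
              cyclic = path$cyclic,
              names = colnames(path$images),
              scales = path$scales,
              images = apply(path$images, 1, function(r) as.list(r),
                             simplify = FALSE))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' Read a string path from JSON
#'
#' @param file JSON path written by [write_string_path()].
#' @return a [string_path()].
#' @export
read_string_path <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = FALSE)
  imgs <- do.call(rbind, lapply(obj$images, function(r) unlist(r)))
  string_path(imgs, cyclic = isTRUE(obj$cyclic),
              names = if (!is.null(obj$names)) unlist(obj$names),
              scales = if (!is.null(obj$scales)) unlist(obj$scales))
}

#' Write a PMF grid as a TSV table
#'
#' One row per bin: bin centers, free energy (NA for masked bins), standard
#' error, occupancy count, and mask flag; `#`-prefixed provenance and header
#' lines.
#'
#' @param pmf a `pmf_grid` from [project_pmf()].
#' @param path output path.
#' @param seed optional seed for the provenance header.
#' @return `path`, invisibly.
#' @export
write_pmf_table <- function(pmf, path, seed = NULL) {
  stopifnot(inherits(pmf, "pmf_grid"))
  if (pmf$dim == 1L) {
    df <- data.frame(xi = pmf$mid, G = pmf$G, se = pmf$se,
                     count = pmf$count, masked = as.integer(pmf$mask))
  } else {
    grid <- expand.grid(xi1 = pmf$mid[[1]], xi2 = pmf$mid[[2]])
    df <- data.frame(grid, G = as.numeric(pmf$G), se = as.numeric(pmf$se),
                     count = as.numeric(pmf$count),
                     masked = as.integer(pmf$mask))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(seed), con)
  writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}
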