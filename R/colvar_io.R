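# Text I/O for collective-variable time series, umbrella-window
# manifests and PMF profiles.

#' Write / read a collective-variable time series
#'
#' Plain-text columnar format: comment lines start with '#', the first
#' column is the integer step and each further column one coordinate.
#' The reader also accepts the multi-space-separated dialect produced
#' by common colvars modules.
#'
#' @param steps Integer step numbers.
#' @param values Numeric vector or matrix (one column per coordinate).
#' @param path Output file.
#' @param names Optional coordinate names for the header comment.
#' @return `path`, invisibly (writer); a data frame with `step` and one
#'   column per coordinate (reader).
#' @export
write_colvar <- function(steps, values, path, names = NULL) {
  values <- as.matrix(values)
  stopifnot(length(steps) == nrow(values))
  if (is.null(names)) names <- paste0("cv", seq_len(ncol(values)))
  header <- paste("#", paste(c("step", names), collapse = " "))
  body <- apply(cbind(steps, values), 1L, function(r)
    paste(c(sprintf("%d", as.integer(r[1])),
            sprintf("%.10g", r[-1])), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(path) {
  lines <- readLines(path)
  names <- NULL
  hdr <- grep("^\\s*#", lines, value = TRUE)
  if (length(hdr)) {
    toks <- strsplit(trimws(sub("^\\s*#", "", hdr[1])), "\\s+")[[1]]
    if (length(toks) > 1L && tolower(toks[1]) == "step") names <- toks[-1]
  }
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in ", path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L)
    stop("ragged colvar file: rows with ", paste(ncol, collapse = "/"),
         " fields")
  m <- do.call(rbind, rows)
  out <- as.data.frame(m)
  cn <- if (!is.null(names) && length(names) == ncol - 1L) names else
    paste0("cv", seq_len(ncol - 1L))
  names(out) <- c("step", cn)
  out$step <- as.integer(out$step)
  out
}

#' Write / read an umbrella-window manifest
#'
#' TSV with columns `index`, `center`, `force_constant` and optionally
#' `file` naming the colvar series holding each window's samples.
#'
#' @param windows A [make_window_grid()] data frame (optionally with a
#'   `file` column).
#' @param path File path.
#' @return `path` invisibly (writer); a `window_grid` data frame
#'   (reader).
#' @export
write_window_manifest <- function(windows, path) {
  utils::write.table(windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_manifest
#' @export
read_window_manifest <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("index", "center", "force_constant")
  if (!all(req %in% names(tb)))
    stop("window manifest needs columns: ", paste(req, collapse = ", "))
  class(tb) <- c("window_grid", "data.frame")
  tb
}

#' Load umbrella-window samples from colvar files
#'
#' @param manifest A window manifest (data frame with a `file` column)
#'   or a path to one.
#' @param dir Directory against which relative file names are resolved.
#' @param column Coordinate column to use (default: the first).
#' @return List of `window_sample` objects ready for [wham()].
#' @export
read_window_samples <- function(manifest, dir = ".", column = 1L) {
  if (is.character(manifest)) manifest <- read_window_manifest(manifest)
  if (is.null(manifest$file))
    stop("manifest lacks a 'file' column")
  lapply(seq_len(nrow(manifest)), function(i) {
    f <- manifest$file[i]
    if (!file.exists(f)) f <- file.path(dir, manifest$file[i])
    cv <- read_colvar(f)
    structure(list(window = list(index = manifest$index[i],
                                 center = manifest$center[i],
                                 force_constant = manifest$force_constant[i]),
                   values = cv[[column + 1L]],
                   source_potential = NULL),
              class = "window_sample")
  })
}

#' Write / read a PMF profile as two-column TSV
#'
#' A `# reference=` comment records the referencing convention.
#'
#' @param pmf A [pmf_profile()].
#' @param path File path.
#' @return `path` invisibly (writer); a [pmf_profile()] (reader).
#' @export
write_pmf <- function(pmf, path) {
  writeLines(c(sprintf("# reference=%s", pmf$reference),
               "# xi\tw_kcal_mol",
               sprintf("%.10g\t%.10g", pmf$grid, pmf$w)), path)
  invisible(path)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(path) {
  lines <- readLines(path)
  ref <- "raw"
  m <- grep("^#\\s*reference=", lines, value = TRUE)
  if (length(m)) ref <- sub("^#\\s*reference=", "", m[1])
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
  # values on file are already referenced; keep them untouched
  p <- pmf_profile(m[, 1], m[, 2], "raw")
  p$reference <- ref
  p
}
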