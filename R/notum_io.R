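#' @name notum_io
#' @title Per-SOP observation tables
#'
#' @description
#' A notum dataset is a tibble with one row per sensory organ progenitor
#' (SOP) and columns:
#'
#' * `notum_id` — which animal/notum the cell belongs to
#' * `row_id` — bristle row within the notum (e.g. `"R1"`)
#' * `side` — `"left"`, `"right"` or `"unspecified"` (serialised as an
#'   empty string)
#' * `position_um` — position along the antero-posterior axis, µm
#'   (anterior = smaller value)
#' * `division_time_min` — division time in minutes from recording start
#' * `genotype` — free-text genotype label
#'
#' Times are kept relative to recording start; rebasing to the first divider
#' (SOP0) is an analysis step ([assign_ranks()]), never done at I/O time.
NULL

NOTUM_COLUMNS <- c("notum_id", "row_id", "side", "position_um",
                   "division_time_min", "genotype")

#' Construct a notum dataset
#'
#' @param records A data frame with the columns documented in [notum_io].
#'   `genotype` and `side` may be omitted (defaulting to `""` and
#'   `"unspecified"`).
#' @param metadata Named list of free-form metadata (genotype, temperature,
#'   APF start, ...), kept as an attribute.
#' @return A tibble of class `notum_dataset`.
#' @export
notum_dataset <- function(records, metadata = list()) {
  records <- tibble::as_tibble(records)
  if (!("genotype" %in% names(records))) records$genotype <- ""
  if (!("side" %in% names(records))) records$side <- "unspecified"
  missing_cols <- setdiff(NOTUM_COLUMNS, names(records))
  if (length(missing_cols) > 0L)
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  records <- records[NOTUM_COLUMNS]
  records$notum_id <- as.character(records$notum_id)
  records$row_id <- as.character(records$row_id)
  records$side <- normalize_side(records$side)
  records$genotype <- as.character(records$genotype)
  structure(records, metadata = metadata,
            class = c("notum_dataset", class(tibble::tibble())))
}

normalize_side <- function(side) {
  side <- as.character(side)
  side[is.na(side) | side == ""] <- "unspecified"
  bad <- !(side %in% c("left", "right", "unspecified"))
  if (any(bad))
    stop("invalid side value(s): ", paste(unique(side[bad]), collapse = ", "),
         call. = FALSE)
  side
}

# Parse numbers accepting both "." and "," as the decimal mark
# (measurement tables in this field use either, e.g. "40,38").
parse_number_dual <- function(x, column, path) {
  x_chr <- trimws(as.character(x))
  comma_dec <- grepl("^-?[0-9]+,[0-9]+([eE][+-]?[0-9]+)?$", x_chr)
  x_chr[comma_dec] <- sub(",", ".", x_chr[comma_dec], fixed = TRUE)
  out <- suppressWarnings(as.numeric(x_chr))
  bad <- which(is.na(out) & !(is.na(x_chr) | x_chr == ""))
  if (length(bad) > 0L)
    stop(sprintf("unparsable numeric value \"%s\" in column '%s' (%s, data line %d)",
                 x_chr[bad[1]], column, path, bad[1]), call. = FALSE)
  out
}

detect_delimiter <- function(header_line) {
  if (grepl("\t", header_line)) "\t"
  else if (grepl(";", header_line)) ";"
  else ","
}

#' Read a per-SOP table from delimited text
#'
#' Auto-detects the delimiter (tab, `;` or `,`) from the header unless
#' `delim` is given. Numeric cells are parsed accepting both `.` and `,` as
#' the decimal mark. Source files with different column names can be read by
#' supplying `col_map`, a named character vector mapping the standard names
#' (see [notum_io]) to the file's column names.
#'
#' @param path Path to a delimited text file with a header.
#' @param delim Field delimiter; `NULL` (default) auto-detects.
#' @param col_map Optional named character vector, e.g.
#'   `c(position_um = "x.position", division_time_min = "T.div")`.
#' @return A [notum_dataset()].
#' @export
read_notum_table <- function(path, delim = NULL, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delimiter(first)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "",
                           stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      src <- col_map[[std]]
      if (!(src %in% names(raw)))
        stop(sprintf("mapped column '%s' (for '%s') not found in %s",
                     src, std, path), call. = FALSE)
      names(raw)[names(raw) == src] <- std
    }
  }
  mandatory <- setdiff(NOTUM_COLUMNS, c("genotype", "side"))
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0L)
    stop(sprintf("%s: missing mandatory column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  raw$position_um <- parse_number_dual(raw$position_um, "position_um", path)
  raw$division_time_min <-
    parse_number_dual(raw$division_time_min, "division_time_min", path)
  notum_dataset(raw, metadata = list(source = path))
}

#' Write a per-SOP table as delimited text
#'
#' The written file round-trips through [read_notum_table()] field-for-field.
#' `side = "unspecified"` is serialised as an empty string.
#'
#' @param dataset A [notum_dataset()] (or compatible data frame).
#' @param path Output path.
#' @param delim Field delimiter (default `,`).
#' @return `path`, invisibly.
#' @export
write_notum_table <- function(dataset, path, delim = ",") {
  dataset <- notum_dataset(dataset,
                           metadata = attr(dataset, "metadata") %||% list())
  out <- as.data.frame(dataset)
  out$side[out$side == "unspecified"] <- ""
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a notum dataset
#'
#' Checks the dataset invariants and reports (never raises): finite
#' positions, finite non-negative division times, uniqueness of
#' `(notum_id, row_id, side, position_um)`, and that every referenced row
#' holds at least two records (a wave needs two cells).
#'
#' @param dataset A [notum_dataset()] (or compatible data frame).
#' @return A character vector of issue descriptions; empty iff the dataset
#'   is valid.
#' @export
validate_dataset <- function(dataset) {
  d <- tibble::as_tibble(dataset)
  issues <- character(0)
  label <- function(i) sprintf("record %d (notum %s, row %s, side %s)",
                               i, d$notum_id[i], d$row_id[i], d$side[i])
  bad_pos <- which(!is.finite(d$position_um))
  for (i in bad_pos)
    issues <- c(issues, paste0(label(i), ": position_um is not finite"))
  bad_t <- which(!is.finite(d$division_time_min) | d$division_time_min < 0)
  for (i in bad_t)
    issues <- c(issues,
                paste0(label(i), ": division_time_min must be finite and >= 0"))
  key <- paste(d$notum_id, d$row_id, d$side, d$position_um, sep = "\r")
  dup <- which(duplicated(key))
  for (i in dup)
    issues <- c(issues,
                paste0(label(i),
                       ": duplicate (notum_id, row_id, side, position_um)"))
  row_key <- paste(d$notum_id, d$row_id, d$side, sep = "/")
  counts <- table(row_key)
  for (k in names(counts)[counts < 2])
    issues <- c(issues,
                sprintf("row %s: only %d record(s); a wave needs >= 2 cells",
                        k, counts[[k]]))
  issues
}
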