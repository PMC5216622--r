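# Delimited-text data model: three input tables (observations, assemblage
# counts, literature size ranges) and their writers. UTF-8 CSV, one header row.
# Species and period labels are arbitrary text, matched by exact equality after
# whitespace trimming; synonymy between cyst and vegetative names is the input
# file's responsibility.

.read_table <- function(path, required) {
  if (!file.exists(path)) {
    ps_stop(sprintf("file not found: %s", path), "paleosize_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE,
                 encoding = "UTF-8", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    ps_stop(sprintf("missing required column(s): %s",
                    paste(missing, collapse = ", ")),
            "paleosize_schema_error")
  }
  df
}

.check_labels <- function(df, cols, path) {
  for (col in cols) {
    df[[col]] <- trimws(as.character(df[[col]]))
    bad <- which(is.na(df[[col]]) | df[[col]] == "")
    if (length(bad) > 0) {
      ps_stop(sprintf("%s: empty '%s' label at line %d", path, col, bad[1] + 1L),
              "paleosize_validation_error")
    }
  }
  df
}

#' Read individual cyst diameter measurements
#'
#' Reads a CSV with columns `species,period,diameter`, one row per measured
#' cyst. Diameters are in micrometres and must be positive.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `species` (character), `period` (character)
#'   and `diameter` (double, μm), one row per measurement, in file order.
#' @seealso [write_observations()], [read_assemblage()], [read_literature()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("species,period,diameter", "A,warm,34.1", "A,cold,38.2"), f)
#' read_observations(f)
read_observations <- function(path) {
  df <- .read_table(path, c("species", "period", "diameter"))
  df <- .check_labels(df, c("species", "period"), path)
  d <- suppressWarnings(as.numeric(df$diameter))
  bad <- which(is.na(d) | d <= 0)
  if (length(bad) > 0) {
    ps_stop(sprintf("%s: non-positive or non-numeric diameter '%s' at line %d",
                    path, df$diameter[bad[1]], bad[1] + 1L),
            "paleosize_validation_error")
  }
  tibble::tibble(species = df$species, period = df$period, diameter = d)
}

#' Read assemblage counts
#'
#' Reads a CSV with columns `species,period,count`: the number of cysts of each
#' species counted in each period's samples. These counts define the relative
#' abundance weights of the community-weighted mean. At most one row per
#' (species, period) pair is allowed.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `species`, `period`, `count` (integer).
#' @export
read_assemblage <- function(path) {
  df <- .read_table(path, c("species", "period", "count"))
  df <- .check_labels(df, c("species", "period"), path)
  n <- suppressWarnings(as.numeric(df$count))
  bad <- which(is.na(n) | n < 0 | n != floor(n))
  if (length(bad) > 0) {
    ps_stop(sprintf("%s: count must be a non-negative integer, got '%s' at line %d",
                    path, df$count[bad[1]], bad[1] + 1L),
            "paleosize_validation_error")
  }
  key <- paste(df$species, df$period, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    ps_stop(sprintf("%s: duplicate (species, period) record: (%s)",
                    path, gsub("\r", ", ", dup, fixed = TRUE)),
            "paleosize_duplicate_error")
  }
  tibble::tibble(species = df$species, period = df$period, count = as.integer(n))
}

.parse_range <- function(lo, hi, what, line, path) {
  lo <- suppressWarnings(as.numeric(lo))
  hi <- suppressWarnings(as.numeric(hi))
  if (is.na(lo) != is.na(hi)) {
    ps_stop(sprintf("%s: %s range needs both min and max at line %d", path, what, line),
            "paleosize_schema_error")
  }
  if (!is.na(lo)) {
    if (lo <= 0 || hi <= 0) {
      ps_stop(sprintf("%s: %s range must be positive at line %d", path, what, line),
              "paleosize_validation_error")
    }
    if (lo > hi) {
      ps_stop(sprintf("%s: %s range min %g > max %g at line %d", path, what, lo, hi, line),
              "paleosize_validation_error")
    }
  }
  c(lo, hi)
}

#' Read literature size ranges
#'
#' Reads a CSV with columns
#' `species,length_min,length_max,width_min,width_max,diameter_min,diameter_max`
#' (μm). Every row must carry either a diameter range, or both a length and a
#' width range from which a diameter range can be derived with
#' [lw_to_diameter()]. Empty cells mean "not reported".
#'
#' A copy of a six-species literature table for Arctic dinoflagellate cysts
#' ships with the package; see `system.file("extdata", "literature_sizes.csv",
#' package = "paleosize")`.
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `species`, `length_min`, `length_max`,
#'   `width_min`, `width_max`, `diameter_min`, `diameter_max`; unreported
#'   ranges are `NA`.
#' @export
read_literature <- function(path) {
  cols <- c("species", "length_min", "length_max", "width_min", "width_max",
            "diameter_min", "diameter_max")
  df <- .read_table(path, cols)
  df <- .check_labels(df, "species", path)
  out <- tibble::tibble(
    species = df$species,
    length_min = NA_real_, length_max = NA_real_,
    width_min = NA_real_, width_max = NA_real_,
    diameter_min = NA_real_, diameter_max = NA_real_
  )
  for (i in seq_len(nrow(df))) {
    line <- i + 1L
    lr <- .parse_range(df$length_min[i], df$length_max[i], "length", line, path)
    wr <- .parse_range(df$width_min[i], df$width_max[i], "width", line, path)
    dr <- .parse_range(df$diameter_min[i], df$diameter_max[i], "diameter", line, path)
    if (is.na(dr[1]) && (is.na(lr[1]) || is.na(wr[1]))) {
      ps_stop(sprintf(
        "%s: row %d (%s) has neither a diameter range nor both length and width ranges",
        path, i, df$species[i]), "paleosize_schema_error")
    }
    out[i, 2:7] <- as.list(c(lr, wr, dr))
  }
  out
}

#' Write the three input tables back to CSV
#'
#' Writers emit the same dialect the readers accept, so that a write/read
#' round trip reproduces the records field for field.
#'
#' @param x A tibble as returned by the corresponding reader.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path) {
  stopifnot(all(c("species", "period", "diameter") %in% names(x)))
  write.csv(x[, c("species", "period", "diameter")], path,
            row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
write_assemblage <- function(x, path) {
  stopifnot(all(c("species", "period", "count") %in% names(x)))
  write.csv(x[, c("species", "period", "count")], path,
            row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_observations
#' @export
write_literature <- function(x, path) {
  cols <- c("species", "length_min", "length_max", "width_min", "width_max",
            "diameter_min", "diameter_max")
  stopifnot(all(cols %in% names(x)))
  write.csv(x[, cols], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
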