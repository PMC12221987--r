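#' Write a table as CSV with a provenance metadata header
#'
#' All pipeline writers share this format: `#`-prefixed `key: value` header
#' lines (seed, scenario, package version, any extra metadata) followed by a
#' regular CSV body. Readers skip the header via the comment character, so
#' the files remain plain CSV to any tool.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param meta Named list of metadata values written into the header.
#' @return `path`, invisibly.
#' @export
pk_write_csv <- function(x, path, meta = list()) {
  meta <- c(list(package = paste0("persisterkit ",
                                  as.character(utils::packageVersion("persisterkit")))),
            meta)
  hdr <- vapply(names(meta), function(k) {
    sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15), collapse = ","))
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [pk_write_csv()]
#'
#' @param path File path.
#' @return Tibble with the parsed header in the `meta` attribute.
#' @export
pk_read_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    k <- sub(":.*$", "", kv)
    v <- sub("^[^:]*:\\s*", "", kv)
    meta[[k]] <- v
  }
  out <- as_tibble(utils::read.csv(text = lines[!grepl("^#", lines)]))
  attr(out, "meta") <- meta
  out
}

#' Read a kill-curve table from CSV
#'
#' Expected schema (documented contract for external data): columns `time`
#' (hours), `cfu` (CFU/ml), `replicate` (1-based id), optional `condition`,
#' `below_detection` (logical), `detection_limit` (CFU/ml). Below-detection
#' rows must carry the limit in `cfu`, never zero.
#'
#' @param path CSV path (plain or with a `#` metadata header).
#' @return Tibble validated against the schema.
#' @export
read_kill_curves <- function(path) {
  x <- pk_read_csv(path)
  need <- c("time", "cfu", "replicate")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("kill-curve CSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(x$time < 0)) abort("negative timepoints in kill-curve CSV")
  if (any(x$cfu < 0)) abort("negative CFU in kill-curve CSV")
  if (!"condition" %in% names(x)) x$condition <- "unknown"
  if (!"below_detection" %in% names(x)) x$below_detection <- FALSE
  x
}

#' Read a single-cell trace table from CSV
#'
#' Expected schema: `cell`, `time` (min), `l` (um), `F` (AU,
#' background-subtracted), `division` (logical flag).
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_traces <- function(path) {
  x <- pk_read_csv(path)
  need <- c("cell", "time", "l", "F")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("trace CSV is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (!"division" %in% names(x)) x$division <- FALSE
  x
}

#' Read a cytometry event table from CSV
#'
#' Expected schema: `fluorescence` (AU); optional `event`, `fsc`,
#' `is_control`.
#'
#' @param path CSV path.
#' @return Tibble.
#' @export
read_event_table <- function(path) {
  x <- pk_read_csv(path)
  if (!"fluorescence" %in% names(x)) {
    abort("event CSV must have a `fluorescence` column")
  }
  if (any(!is.finite(x$fluorescence))) abort("non-finite fluorescence values")
  x
}
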