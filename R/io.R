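# Readers and writers for the pipeline's table, report and image formats.
# CSV vs TSV is chosen by file extension; reports are deterministic
# (sorted keys, fixed float formatting) so identical inputs give
# byte-identical files.

.delim_for <- function(path) {
  if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
}

#' Read a compression-record table
#'
#' Reads per-compression measurements (CSV by `.csv` extension, otherwise
#' TSV) with mandatory header columns `aggregate_id`, `step`, `F_dyn`,
#' `X_um`, `R2_um`, `H_um`. Every row is validated against the profile
#' invariants; the side-arc radius `R1_um` is always derived (never read)
#' and the profile volume `V_um3` is filled in when absent.
#'
#' @param path Path to the table.
#' @return Validated data frame of compression records with derived
#'   `R1_um` and `V_um3` columns.
#' @export
read_compression_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          stringsAsFactors = FALSE)
  req <- c("aggregate_id", "step", "F_dyn", "X_um", "R2_um", "H_um")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    stop("schema error: missing column ", paste(miss, collapse = ", "))
  }
  df$R1_um <- NA_real_
  if (!"V_um3" %in% names(df)) df$V_um3 <- NA_real_
  for (i in seq_len(nrow(df))) {
    if (!df$step[i] %in% c(1, 2)) {
      stop("row-level error for aggregate ", df$aggregate_id[i],
           ": step must be 1 or 2")
    }
    if (!is.finite(df$F_dyn[i]) || df$F_dyn[i] < 0) {
      stop("row-level error for aggregate ", df$aggregate_id[i],
           ": invalid force")
    }
    prof <- tryCatch(
      aggregate_profile(X = df$X_um[i], R2 = df$R2_um[i], H = df$H_um[i]),
      error = function(e) {
        stop("row-level error for aggregate ", df$aggregate_id[i], ": ",
             conditionMessage(e))
      })
    df$R1_um[i] <- prof$R1
    if (!is.finite(df$V_um3[i])) df$V_um3[i] <- profile_volume(profile = prof)
  }
  df
}

#' Write a compression-record table
#'
#' @param records Data frame of compression records.
#' @param path Output path; `.csv` writes comma-separated, anything else
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_compression_table <- function(records, path) {
  utils::write.table(records, path, sep = .delim_for(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a compaction series as TSV
#'
#' @param series A `"compaction_series"` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_compaction_series <- function(series, path) {
  utils::write.table(as.data.frame(series)[, c("t_day", "area_rel", "Fn_ug_ml")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# deterministic provenance block: package version + a hash of the payload
.provenance <- function(x) {
  list(package = "tstkit",
       version = as.character(utils::packageVersion("tstkit")),
       config_hash = .stable_hash(x))
}

# small stable polynomial rolling hash of the serialized payload (hex)
.stable_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(utils::capture.output(utils::str(x)),
                                      collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# round every numeric leaf to 6 significant digits for stable serialization
.signif_leaves <- function(x, digits = 6) {
  if (is.list(x)) return(lapply(x, .signif_leaves, digits = digits))
  if (is.numeric(x)) return(signif(x, digits))
  x
}

#' Write an analysis report
#'
#' Serializes cohort statistics (or any named stats structure) as JSON or
#' TSV, deterministically: keys sorted, floats at 6 significant digits, and
#' a provenance block (package version, config hash) embedded. Identical
#' inputs produce byte-identical files.
#'
#' @param stats A `cohort_stats` object, data frame, or named list of
#'   numeric/character fields (possibly nested for JSON).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(stats, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (inherits(stats, "cohort_stats")) stats <- as.data.frame(unclass(stats))
  if (format == "json") {
    payload <- if (is.data.frame(stats)) stats else .signif_leaves(stats)
    if (is.data.frame(payload)) {
      payload <- payload[, sort(names(payload)), drop = FALSE]
      num <- vapply(payload, is.numeric, logical(1))
      payload[num] <- lapply(payload[num], signif, 6)
    } else if (is.list(payload) && !is.null(names(payload))) {
      payload <- payload[sort(names(payload))]
    }
    out <- list(provenance = .provenance(payload), report = payload)
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    if (!is.data.frame(stats)) stats <- as.data.frame(stats)
    stats <- stats[, sort(names(stats)), drop = FALSE]
    num <- vapply(stats, is.numeric, logical(1))
    stats[num] <- lapply(stats[num], signif, 6)
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(paste0("# tstkit ", utils::packageVersion("tstkit"),
                      " config_hash=", .stable_hash(stats)), con)
    utils::write.table(stats, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read back a JSON report
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return List with `provenance` and `report`.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write an 8-bit grayscale image
#'
#' PNG or TIFF chosen by extension.
#'
#' @param image Integer/numeric matrix with values in 0-255, or a
#'   `"fiber_image"` (its `$image` is written).
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (inherits(image, "fiber_image")) image <- image$image
  .check_gray(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image / 255, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' Read an 8-bit grayscale image
#'
#' @param path PNG or TIFF path.
#' @return Integer matrix with values in 0-255.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] >= 3 &&
        !all(arr[, , 1] == arr[, , 2] & arr[, , 2] == arr[, , 3])) {
      stop("unsupported image: not grayscale")
    }
    arr <- arr[, , 1]
  }
  out <- round(arr * 255)
  storage.mode(out) <- "integer"
  out
}

#' Write fiber ground truth sidecar
#'
#' JSON sidecar with the generator's true per-fiber lengths and calibration,
#' for validating morphometry output against ground truth.
#'
#' @param fibers A `"fiber_image"` from [generate_fiber_image()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fiber_truth <- function(fibers, path) {
  stopifnot(inherits(fibers, "fiber_image"))
  jsonlite::write_json(
    list(n_fibers = length(fibers$lengths_um),
         pixel_size_um = fibers$pixel_size,
         lengths_um = fibers$lengths_um),
    path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
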