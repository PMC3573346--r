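#' Read phase angles from a text file
#'
#' Accepts either a plain single-column file (one angle per line, `#`
#' comment lines ignored) or a delimited CSV/TSV file with a header, in
#' which case `column` names the column to read. Degrees are converted to
#' radians at this boundary; everything downstream works in radians.
#'
#' @param path Path to the file.
#' @param column Column name for delimited files with a header; `NULL`
#'   (default) for single-column files.
#' @param units `"radians"` (default) or `"degrees"`.
#'
#' @return An [angle_sample]; the label is the column name, or the file
#'   stem for single-column files.
#'
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0.0", "3.14159"), f)
#' read_angles(f)
#' @export
read_angles <- function(path, column = NULL, units = c("radians", "degrees")) {
  units <- match.arg(units)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(column)) {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    raw <- trimws(lines[keep])
    vals <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(vals))
    if (length(bad) > 0L) {
      stop(sprintf(
        "non-numeric entry \"%s\" at line %d of %s",
        raw[bad[1]], which(keep)[bad[1]], path
      ), call. = FALSE)
    }
    if (length(vals) == 0L) {
      stop(sprintf("no angles found in %s", path), call. = FALSE)
    }
    label <- sub("\\.[^.]*$", "", basename(path))
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- utils::read.table(path,
      header = TRUE, sep = sep,
      comment.char = "#", check.names = FALSE
    )
    if (!column %in% names(df)) {
      stop(sprintf(
        "column \"%s\" not found in %s (columns: %s)", column, path,
        paste(names(df), collapse = ", ")
      ), call. = FALSE)
    }
    vals <- df[[column]]
    if (!is.numeric(vals)) {
      stop(sprintf("column \"%s\" in %s is not numeric", column, path),
        call. = FALSE
      )
    }
    label <- column
  }
  if (units == "degrees") vals <- vals * pi / 180
  angle_sample(vals, label = label)
}

#' Write phase angles to a plain text file
#'
#' One angle per line (radians), with the sample label as a `#` comment
#' header. Round-trips through [read_angles()].
#'
#' @param sample An [angle_sample].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_angles <- function(sample, path) {
  sample <- as_angle_sample(sample)
  lab <- attr(sample, "label")
  lines <- format(as.numeric(sample), digits = 17, trim = TRUE)
  if (!is.null(lab)) lines <- c(sprintf("# label: %s", lab), lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read a multi-channel trial array from delimited matrices
#'
#' Assembles a [trial_array] from one delimited matrix per channel
#' (rows = trials, columns = samples; no header) plus a JSON sidecar with
#' at least `fs` (Hz) and optionally `t0` (seconds) and `channel_names`.
#' Channel order follows `matrix_paths` (or the sidecar's `channel_names`
#' ordering when both are given, which must agree in length).
#'
#' @param matrix_paths Character vector of per-channel matrix files
#'   (CSV, or TSV when the extension is `.tsv`).
#' @param sidecar_path Path to the JSON sidecar.
#'
#' @return A [trial_array].
#' @export
read_trials <- function(matrix_paths, sidecar_path) {
  stopifnot(length(matrix_paths) >= 1L)
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$fs)) {
    stop(sprintf("sidecar %s is missing `fs`", sidecar_path), call. = FALSE)
  }
  if (!is.numeric(meta$fs) || meta$fs <= 0) {
    stop("`fs` in the sidecar must be a positive number", call. = FALSE)
  }
  mats <- lapply(matrix_paths, function(p) {
    sep <- if (grepl("\\.tsv$", p, ignore.case = TRUE)) "\t" else ","
    as.matrix(utils::read.table(p, header = FALSE, sep = sep))
  })
  d1 <- dim(mats[[1]])
  for (i in seq_along(mats)[-1]) {
    if (!identical(dim(mats[[i]]), d1)) {
      stop(sprintf(
        "shape mismatch: %s is %dx%d but %s is %dx%d",
        matrix_paths[1], d1[1], d1[2],
        matrix_paths[i], nrow(mats[[i]]), ncol(mats[[i]])
      ), call. = FALSE)
    }
  }
  data <- array(0, c(d1[1], length(mats), d1[2]))
  for (i in seq_along(mats)) data[, i, ] <- mats[[i]]
  trial_array(data,
    fs = meta$fs, t0 = if (is.null(meta$t0)) 0 else meta$t0,
    channel_names = meta$channel_names
  )
}

#' Write a trial array as delimited matrices plus a JSON sidecar
#'
#' Inverse of [read_trials()]: one CSV per channel under `dir`
#' (`channel_<name>.csv`, rows = trials, columns = samples) and a
#' `sidecar.json` carrying `fs`, `t0` and `channel_names`.
#'
#' @param trials A [trial_array].
#' @param dir Output directory (created if needed).
#' @return Named list with `matrix_paths` and `sidecar_path`, invisibly.
#' @export
write_trials <- function(trials, dir) {
  stopifnot(inherits(trials, "trial_array"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(trials$data)
  names <- trials$channel_names %||% sprintf("ch%d", seq_len(d[2]))
  paths <- file.path(dir, sprintf("channel_%s.csv", names))
  for (i in seq_len(d[2])) {
    utils::write.table(matrix(trials$data[, i, ], d[1], d[3]), paths[i],
      sep = ",", row.names = FALSE, col.names = FALSE
    )
  }
  sidecar <- file.path(dir, "sidecar.json")
  jsonlite::write_json(
    list(fs = trials$fs, t0 = trials$t0, channel_names = names),
    sidecar,
    auto_unbox = TRUE, digits = NA
  )
  invisible(list(matrix_paths = paths, sidecar_path = sidecar))
}

#' Serialize a result object
#'
#' Writes a [test_result] or `roc_result` to JSON (stable, documented
#' keys) or a `roc_result` / benchmark table to TSV. JSON test results
#' round-trip through [read_result()].
#'
#' @param result A `test_result`, `roc_result`, or a benchmark data.frame.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- if (inherits(result, "test_result")) {
      c(class = "test_result", unclass(result))
    } else if (inherits(result, "roc_result")) {
      c(class = "roc_result", unclass(result))
    } else {
      stop("JSON output supports test_result and roc_result objects",
        call. = FALSE
      )
    }
    jsonlite::write_json(payload, path,
      auto_unbox = TRUE, digits = NA,
      null = "null", dataframe = "columns"
    )
  } else {
    tab <- if (inherits(result, "roc_result")) {
      result$points
    } else if (is.data.frame(result)) {
      result
    } else {
      stop("TSV output supports roc_result objects and data.frames",
        call. = FALSE
      )
    }
    utils::write.table(tab, path,
      sep = "\t", row.names = FALSE,
      quote = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_result
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- x$class
  x$class <- NULL
  if (identical(cls, "test_result")) {
    return(test_result(x$method, x$statistic, x$p_value,
      n1 = x$n1, n2 = x$n2,
      mode = x$mode, n_permutations = x$n_permutations, seed = x$seed,
      extra = x$extra
    ))
  }
  if (identical(cls, "roc_result")) {
    return(structure(
      list(
        points = as.data.frame(x$points), auc = x$auc,
        auc_sd = x$auc_sd %||% NA_real_, n_pos = x$n_pos, n_neg = x$n_neg
      ),
      class = "roc_result"
    ))
  }
  stop(sprintf("unrecognised result file: %s", path), call. = FALSE)
}

#' Run manifest for reproducibility
#'
#' Records what a pipeline run did: the package version, the entry point,
#' the fully resolved configuration and every seed consumed, so the run
#' can be repeated identically. The command-line wrapper writes one next
#' to each output it produces.
#'
#' @param subcommand Name of the entry point (e.g. `"simulate"`).
#' @param resolved_config Named list of resolved parameters.
#' @param seeds Named list of the seeds used per stage.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(subcommand, resolved_config, seeds, path) {
  jsonlite::write_json(
    list(
      tool_version = as.character(utils::packageVersion("ustpl")),
      subcommand = subcommand,
      resolved_config = resolved_config,
      seeds = seeds,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
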