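#' Write a hemoglobin recording to CSV/TSV
#'
#' Column convention: first column `time` in seconds, then one column per
#' channel per chromophore named `HbO_01 ... HbO_nn`, `HbR_01 ...`,
#' `HbT_01 ...`, plus a 0/1 `valid` column for the sample mask. Values
#' are written at full round-trippable precision.
#'
#' @param rec an `hb_recording`.
#' @param path output file; a `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "hb_recording"))
  n_ch <- n_channels(rec)
  n_s <- n_samples(rec)
  # %.17g guarantees a bit-exact numeric round trip through text
  fmt <- function(x) sprintf("%.17g", x)
  df <- data.table::data.table(time = fmt((seq_len(n_s) - 1) * rec$sampling_interval))
  for (pref in c("HbO", "HbR", "HbT")) {
    mat <- switch(pref, HbO = rec$oxy, HbR = rec$deoxy, HbT = rec$total)
    for (ch in seq_len(n_ch))
      df[[sprintf("%s_%02d", pref, ch)]] <- fmt(mat[ch, ])
  }
  df$valid <- as.integer(rec$valid_mask)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

parse_channel_columns <- function(cols, prefix) {
  hit <- grep(sprintf("^%s_\\d+$", prefix), cols, value = TRUE)
  if (length(hit) == 0) return(NULL)
  idx <- as.integer(sub(sprintf("^%s_", prefix), "", hit))
  hit[order(idx)]
}

#' Read a recording from CSV/TSV
#'
#' Parses the column convention of [write_recording()]: a `time` column
#' (seconds; the sampling interval is taken as the median time step) or,
#' failing that, a `sampling_interval` stated by the caller; chromophore
#' channel columns prefixed `HbO_`, `HbR_`, `HbT_`; and an optional
#' `valid` column. A missing `HbT` block is synthesized as `HbO + HbR`
#' with a message. Columns named `OD780_`, `OD805_`, `OD830_` instead
#' yield an `od_recording`.
#'
#' @param path input file.
#' @param format `"csv"`, `"tsv"` (inferred from the extension by
#'   default) or `"snirf"` (not supported in this build).
#' @param sampling_interval used only when the file has no `time` column.
#' @return an `hb_recording` or `od_recording`.
#' @export
read_recording <- function(path, format = NULL, sampling_interval = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "tsv"
              else if (grepl("\\.snirf$", path, ignore.case = TRUE)) "snirf"
              else "csv"
  if (format == "snirf")
    stop("SNIRF input is not supported in this build; ",
         "convert to the CSV/TSV channel-column format instead")
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = if (format == "tsv") "\t" else ",",
                          data.table = FALSE)
  if ("time" %in% names(df)) {
    steps <- diff(df$time)
    if (length(steps) == 0 || any(steps <= 0))
      stop("malformed 'time' column: must be strictly increasing")
    dt <- stats::median(steps)
  } else if (!is.null(sampling_interval)) {
    dt <- sampling_interval
  } else {
    stop("no 'time' column and no sampling_interval supplied")
  }

  od_cols <- lapply(c("OD780", "OD805", "OD830"), function(p)
    parse_channel_columns(names(df), p))
  if (all(!vapply(od_cols, is.null, logical(1)))) {
    n_ch <- length(od_cols[[1]])
    if (!all(vapply(od_cols, length, integer(1)) == n_ch))
      stop("inconsistent channel counts across OD wavelength columns")
    od <- array(0, dim = c(3, n_ch, nrow(df)))
    for (w in 1:3) od[w, , ] <- t(as.matrix(df[od_cols[[w]]]))
    return(od_recording(od, wavelengths = c(780, 805, 830),
                        sampling_interval = dt))
  }

  hbo_cols <- parse_channel_columns(names(df), "HbO")
  hbr_cols <- parse_channel_columns(names(df), "HbR")
  hbt_cols <- parse_channel_columns(names(df), "HbT")
  if (is.null(hbo_cols) || is.null(hbr_cols))
    stop("no HbO_/HbR_ channel columns found in ", path)
  if (length(hbo_cols) != length(hbr_cols))
    stop("inconsistent channel counts: ", length(hbo_cols), " HbO vs ",
         length(hbr_cols), " HbR columns")
  oxy <- unname(t(as.matrix(df[hbo_cols])))
  deoxy <- unname(t(as.matrix(df[hbr_cols])))
  total <- if (is.null(hbt_cols)) {
    message("no HbT columns; synthesizing total = HbO + HbR")
    NULL
  } else {
    if (length(hbt_cols) != length(hbo_cols))
      stop("inconsistent channel counts for HbT columns")
    unname(t(as.matrix(df[hbt_cols])))
  }
  valid <- if ("valid" %in% names(df)) df$valid != 0 else NULL
  hb_recording(oxy = oxy, deoxy = deoxy, total = total,
               sampling_interval = dt, valid_mask = valid,
               channel_labels = sub("^HbO_", "CH", hbo_cols))
}

#' Read a cohort table from CSV
#'
#' Expects columns `subject_id`, `age_years`, optionally `sex`, and
#' either a precomputed `abc_total` or the 57 item columns
#' `abc_item_01 ... abc_item_57` (0/1), which are scored against the
#' package weight table.
#'
#' @param path CSV file.
#' @return data.frame with at least `subject_id`, `age_years`,
#'   `abc_total`.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, data.table = FALSE)
  for (col in c("subject_id", "age_years")) {
    if (!col %in% names(df))
      stop("cohort table is missing required column: ", col)
  }
  if (anyDuplicated(df$subject_id))
    stop("cohort table has duplicated subject ids")
  if (any(df$age_years <= 0)) stop("ages must be positive")
  if (!"abc_total" %in% names(df)) {
    item_cols <- sprintf("abc_item_%02d", 1:57)
    if (!all(item_cols %in% names(df)))
      stop("cohort table is missing column: abc_total ",
           "(and no complete abc_item_01..57 block to score)")
    df$abc_total <- apply(df[item_cols], 1,
                          function(r) score_abc(as.logical(r))$total)
  }
  df
}

#' Write a generated cohort to disk
#'
#' Writes `cohort.csv`, per-subject recording CSVs
#' (`recording_<id>.csv`) and the planted ground truth
#' (`truth.json`: densities and per-subject seeds) into a directory.
#'
#' @param cohort_bundle result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort_bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(cohort_bundle$cohort, file.path(dir, "cohort.csv"))
  if (!is.null(cohort_bundle$recordings)) {
    for (id in names(cohort_bundle$recordings))
      write_recording(cohort_bundle$recordings[[id]],
                      file.path(dir, sprintf("recording_%s.csv", id)))
  }
  truth <- list(density = cohort_bundle$truth$density,
                subject_seeds = cohort_bundle$truth$subject_seeds)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
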