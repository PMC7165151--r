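#' Per-sample clinical annotation
#'
#' Validates and types the clinical table used throughout the pipeline.
#' Recognized columns (all but `sample_id` optional): `histology`
#' (diffuse/intestinal/normal), `pcc` (poorly cohesive carcinoma flag),
#' `age`, `sex`, `ajcc_stage` (I-IV; substages such as IIIb collapse to the
#' main stage), `tumor_site` (cardia/body/antrum/whole), `chemo` (adjuvant
#' chemotherapy flag), `dfs_time`/`dfs_event`, `os_time`/`os_event` (months,
#' 0/1 event indicators), `molecular_subtype` (EBV/MSI/GS/CIN). Unknown
#' columns are carried through unchanged.
#'
#' @param df A data.frame with at least a `sample_id` column.
#' @return A data.frame of class `"cohort_annotation"`, sorted by `sample_id`.
#' @export
cohort_annotation <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) stop("clinical table needs a 'sample_id' column",
                                        call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }

  chk_enum <- function(x, levels, what) {
    x <- tolower(trimws(as.character(x)))
    x[x %in% c("", "na")] <- NA_character_
    bad <- setdiff(unique(x[!is.na(x)]), levels)
    if (length(bad) > 0) stop("invalid ", what, " value(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    x
  }
  as_flag <- function(x, what) {
    if (is.logical(x)) return(x)
    x <- tolower(trimws(as.character(x)))
    x[x %in% c("", "na")] <- NA_character_
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "yes", "y")] <- TRUE
    out[x %in% c("0", "false", "no", "n")] <- FALSE
    if (any(!is.na(x) & is.na(out))) stop("invalid ", what, " flag value(s): ",
                                          paste(unique(x[!is.na(x) & is.na(out)]),
                                                collapse = ", "), call. = FALSE)
    out
  }

  if ("histology" %in% names(df)) {
    df$histology <- chk_enum(df$histology, c("diffuse", "intestinal", "normal"),
                             "histology")
  }
  if ("pcc" %in% names(df)) df$pcc <- as_flag(df$pcc, "pcc")
  if ("chemo" %in% names(df)) df$chemo <- as_flag(df$chemo, "chemo")
  if ("sex" %in% names(df)) df$sex <- chk_enum(df$sex, c("male", "female"), "sex")
  if ("age" %in% names(df)) {
    df$age <- as.numeric(df$age)
    if (any(df$age < 0, na.rm = TRUE)) stop("negative age", call. = FALSE)
  }
  if ("ajcc_stage" %in% names(df)) df$ajcc_stage <- normalize_stage(df$ajcc_stage)
  if ("tumor_site" %in% names(df)) {
    df$tumor_site <- chk_enum(df$tumor_site, c("cardia", "body", "antrum", "whole"),
                              "tumor_site")
  }
  if ("molecular_subtype" %in% names(df)) {
    ms <- toupper(trimws(as.character(df$molecular_subtype)))
    ms[ms %in% c("", "NA")] <- NA_character_
    bad <- setdiff(unique(ms[!is.na(ms)]), c("EBV", "MSI", "GS", "CIN"))
    if (length(bad) > 0) stop("invalid molecular_subtype value(s): ",
                              paste(bad, collapse = ", "), call. = FALSE)
    df$molecular_subtype <- ms
  }

  for (ep in c("dfs", "os")) {
    tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
    if (tcol %in% names(df)) {
      df[[tcol]] <- as.numeric(df[[tcol]])
      if (any(df[[tcol]] < 0, na.rm = TRUE)) {
        stop("negative ", tcol, " for sample(s): ",
             paste(df$sample_id[which(df[[tcol]] < 0)], collapse = ", "),
             call. = FALSE)
      }
    }
    if (ecol %in% names(df)) {
      df[[ecol]] <- as_flag(df[[ecol]], ecol)
      has_event <- !is.na(df[[ecol]])
      has_time <- tcol %in% names(df) && length(df[[tcol]]) > 0
      missing_time <- if (has_time) is.na(df[[tcol]]) else rep(TRUE, nrow(df))
      if (any(has_event & missing_time)) {
        stop(ecol, " present without ", tcol, " for sample(s): ",
             paste(df$sample_id[has_event & missing_time], collapse = ", "),
             call. = FALSE)
      }
    }
  }

  df <- df[order(df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cohort_annotation", "data.frame")
  df
}

# Collapse AJCC substages (IA, IIIb, ...) to the main stage and return an
# ordered factor I < II < III < IV.
normalize_stage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "NA")] <- NA_character_
  main <- sub("^(IV|III|II|I).*$", "\\1", x)
  bad <- !is.na(x) & !main %in% c("I", "II", "III", "IV")
  if (any(bad)) stop("unparseable AJCC stage value(s): ",
                     paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  factor(main, levels = c("I", "II", "III", "IV"), ordered = TRUE)
}

#' Read a clinical annotation TSV
#'
#' @param path Path to a tab-delimited file with a `sample_id` column; see
#'   [cohort_annotation()] for recognized columns.
#' @return A `cohort_annotation` data.frame.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", ""))
  cohort_annotation(df)
}

#' Write a clinical annotation TSV
#'
#' @param annot A `cohort_annotation` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical_table <- function(annot, path) {
  out <- as.data.frame(annot)
  if ("ajcc_stage" %in% names(out)) out$ajcc_stage <- as.character(out$ajcc_stage)
  for (col in names(out)) if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
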