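#' Construct a Cq matrix
#'
#' A `cq_matrix` holds raw quantification-cycle (Cq) values from a qPCR
#' array, assays in rows and samples in columns. Non-detected reactions
#' ("Undetermined" wells or values above the instrument ceiling) are stored
#' as `NA`, an explicit sentinel kept distinct from any numeric Cq: imputing
#' a ceiling value such as 40 would contaminate group means, and the
#' detection logic downstream treats non-detection categorically.
#'
#' @param values Numeric matrix with unique rownames (assay ids) and unique
#'   colnames (sample ids). `NA` marks non-detection. Numeric entries must
#'   satisfy `0 < Cq <= 40`.
#' @return An object of class `cq_matrix` (a numeric matrix).
#' @export
cq_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  an <- rownames(values)
  sn <- colnames(values)
  if (is.null(an) || anyNA(an) || any(an == "")) {
    stop("assay ids (rownames) must be present and non-empty", call. = FALSE)
  }
  if (is.null(sn) || anyNA(sn) || any(sn == "")) {
    stop("sample ids (colnames) must be present and non-empty", call. = FALSE)
  }
  if (anyDuplicated(an)) {
    stop("duplicate assay id(s): ",
         paste(unique(an[duplicated(an)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sn)) {
    stop("duplicate sample id(s): ",
         paste(unique(sn[duplicated(sn)]), collapse = ", "), call. = FALSE)
  }
  num <- values[!is.na(values)]
  if (length(num) && (any(num <= 0) || any(num > 40))) {
    stop("numeric Cq values must satisfy 0 < Cq <= 40", call. = FALSE)
  }
  structure(values, class = c("cq_matrix", class(values)))
}

#' @export
print.cq_matrix <- function(x, ...) {
  cat(sprintf("cq_matrix: %d assays x %d samples (%d non-detected cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  if (nrow(x) > 6L || ncol(x) > 8L) {
    print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(8L, ncol(x))),
                     drop = FALSE])
    cat("...\n")
  } else {
    print(unclass(x))
  }
  invisible(x)
}

.detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else if (grepl(",", first)) ","
  else stop("cannot detect delimiter (expected tab or comma) in ", path,
            call. = FALSE)
}

#' Read a Cq matrix from a delimited text file
#'
#' First column is the assay id; each remaining column is one sample.
#' Delimiter (tab or comma) is auto-detected. Cells matching one of
#' `sentinel_tokens` become the non-detection sentinel (`NA`); any other
#' non-numeric cell is a hard error. Numeric parsing is locale-independent
#' (dot decimal separator).
#'
#' @param path Path to a CSV/TSV file.
#' @param sentinel_tokens Character vector of tokens mapped to non-detection.
#' @return A [cq_matrix].
#' @export
read_cq_matrix <- function(path, sentinel_tokens = c("Undetermined", "NA", "")) {
  delim <- .detect_delim(path)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           comment.char = "", quote = "\"",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("Cq matrix file needs an assay column plus at least one sample column", call. = FALSE)
  assays <- raw[[1L]]
  if (anyDuplicated(assays)) {
    stop("duplicate assay id(s) in ", path, ": ",
         paste(unique(assays[duplicated(assays)]), collapse = ", "),
         call. = FALSE)
  }
  samples <- colnames(raw)[-1L]
  vals <- matrix(NA_real_, nrow = length(assays), ncol = length(samples),
                 dimnames = list(assays, samples))
  for (j in seq_along(samples)) {
    cell <- trimws(raw[[j + 1L]])
    is_sent <- cell %in% sentinel_tokens
    num <- suppressWarnings(as.numeric(cell))
    bad <- !is_sent & is.na(num)
    if (any(bad)) {
      i <- which(bad)[1L]
      stop(sprintf("non-numeric, non-sentinel Cq value %s at assay '%s', sample '%s'",
                   dQuote(cell[i]), assays[i], samples[j]), call. = FALSE)
    }
    num[is_sent] <- NA_real_
    vals[, j] <- num
  }
  cq_matrix(vals)
}

#' Write a Cq matrix to a delimited text file
#'
#' Inverse of [read_cq_matrix()]: sentinel cells are written as `sentinel`
#' so that a read/write round trip is lossless.
#'
#' @param x A [cq_matrix].
#' @param path Output path.
#' @param sep Field delimiter.
#' @param sentinel Token written for non-detected cells.
#' @export
write_cq_matrix <- function(x, path, sep = "\t", sentinel = "Undetermined") {
  stopifnot(inherits(x, "cq_matrix"))
  chr <- matrix(as.character(unclass(x)), nrow = nrow(x),
                dimnames = dimnames(x))
  chr[is.na(x)] <- sentinel
  df <- data.frame(assay = rownames(x), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.CELL_TYPES <- c("PSC", "NSC", "FPP")
.COMPARTMENTS <- c("IN", "EV")

#' Read and validate a sample sheet
#'
#' The sheet must carry columns `sample_id`, `donor`, `cell_type`
#' (PSC/NSC/FPP) and `compartment` (IN/EV). Group labels are normalized to
#' canonical upper case. When `cq` is supplied, every matrix sample must be
#' annotated.
#'
#' @param path Path to a CSV/TSV sample sheet.
#' @param cq Optional [cq_matrix] to validate against.
#' @return A data.frame of annotations with an added `group` column
#'   (`<cell_type>_<compartment>`).
#' @export
read_sample_sheet <- function(path, cq = NULL) {
  delim <- .detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  validate_sample_sheet(df, cq = cq)
}

#' Validate sample annotations against a Cq matrix
#'
#' @param df data.frame with columns sample_id, donor, cell_type, compartment.
#' @param cq Optional [cq_matrix]; every matrix sample must then appear
#'   exactly once in `df`.
#' @return The validated, normalized annotation data.frame.
#' @export
validate_sample_sheet <- function(df, cq = NULL) {
  need <- c("sample_id", "donor", "cell_type", "compartment")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) {
    stop("sample sheet is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, need]
  df$cell_type <- toupper(trimws(df$cell_type))
  df$compartment <- toupper(trimws(df$compartment))
  bad_ct <- setdiff(unique(df$cell_type), .CELL_TYPES)
  if (length(bad_ct)) {
    stop("unknown cell_type value(s): ", paste(bad_ct, collapse = ", "),
         call. = FALSE)
  }
  bad_cp <- setdiff(unique(df$compartment), .COMPARTMENTS)
  if (length(bad_cp)) {
    stop("unknown compartment value(s): ", paste(bad_cp, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(cq)) {
    orphan <- setdiff(colnames(cq), df$sample_id)
    if (length(orphan)) {
      stop("sample(s) present in Cq matrix but missing from sample sheet: ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
  }
  df$group <- paste(df$cell_type, df$compartment, sep = "_")
  df
}

#' Derive a sample sheet from structured sample ids
#'
#' Parses ids of the form `<cell_type>_<compartment>_<donor>` (e.g.
#' `"PSC_EV_C1"`) into a validated annotation data.frame.
#'
#' @param sample_ids Character vector of structured sample ids.
#' @return Annotation data.frame as from [read_sample_sheet()].
#' @export
sample_sheet_from_ids <- function(sample_ids) {
  parts <- strsplit(sample_ids, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("sample id(s) not of the form <cell_type>_<compartment>_<donor>: ",
         paste(sample_ids[bad], collapse = ", "), call. = FALSE)
  }
  m <- do.call(rbind, parts)
  validate_sample_sheet(data.frame(
    sample_id = sample_ids, donor = m[, 3L], cell_type = m[, 1L],
    compartment = m[, 2L], stringsAsFactors = FALSE))
}

#' Read a two-column mapping table (miRNA-to-gene or gene-to-pathway)
#'
#' Tab- or comma-delimited with a header. miRNA-to-gene tables need columns
#' `mirna_id` and `gene_id`; gene-to-pathway tables need `gene_id`,
#' `pathway_id` and optionally `pathway_name`. Duplicate pairs are dropped.
#'
#' @param path Path to the table.
#' @return data.frame of unique mapping records.
#' @export
read_mapping_table <- function(path) {
  delim <- .detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = TRUE,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty mapping table: ", path, call. = FALSE)
  if (any(df == "" | is.na(df))) {
    stop("mapping table has empty identifier(s): ", path, call. = FALSE)
  }
  unique(df)
}

#' Canonicalize miRNA identifiers
#'
#' Lower-cases, strips an organism prefix ("hsa-"), and preserves the arm
#' suffix (-5p/-3p). Published lists mix spellings such as "miR-137" and
#' "hsa-miR-137"; canonicalization makes set operations on them exact.
#'
#' @param x Character vector of miRNA names.
#' @return Canonical names (e.g. "mir-218-5p").
#' @export
canonicalize_mirna <- function(x) {
  x <- tolower(trimws(x))
  sub("^hsa-", "", x)
}
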