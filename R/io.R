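# CSV and JSON input/output.
#
# The biometry CSV schema mirrors the tomographer export: required columns
# laterality, Ra, Qa, Rp, Qp, CCT, ACD, Pup, Pup_X, Pup_Y (mm / unitless),
# optional I_X, I_Y (degrees) and an optional free-text `status` column
# used for exclusion filtering (pseudophakia, mydriasis, ectasia,
# incomplete records). Header matching is case-insensitive; comma or
# semicolon dialects are supported.

BIOMETRY_COLUMNS <- c("laterality", "Ra", "Qa", "Rp", "Qp", "CCT", "ACD",
                      "Pup", "Pup_X", "Pup_Y")

#' Read and validate a biometry CSV table
#'
#' Reads the table, normalises headers case-insensitively to the canonical
#' names, optionally filters rows whose `status` matches an exclusion
#' pattern (counts are reported via [message()]), checks units for
#' plausibility, rejects rows violating the biometry invariants with
#' row-indexed messages, and left-normalises lateralities.
#'
#' @param path CSV file.
#' @param sep field separator (`","` or `";"`); with `";"`, a decimal
#'   comma is assumed (`dec = ","`), matching the common clinical export
#'   locale.
#' @param dec decimal mark; default chosen from `sep`.
#' @param exclude_status character vector of status patterns to drop
#'   (case-insensitive substring match); `NULL` disables filtering.
#' @param normalise left-normalise right eyes (default TRUE).
#' @return validated biometry data.frame (plus any optional columns).
#' @export
read_biometry_csv <- function(path, sep = ",",
                              dec = if (sep == ";") "," else ".",
                              exclude_status = c("pseudophak", "mydriasis",
                                                 "ectasia", "keratoconus",
                                                 "incomplete"),
                              normalise = TRUE) {
  raw <- utils::read.table(path, header = TRUE, sep = sep, dec = dec,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  lut <- stats::setNames(
    c(BIOMETRY_COLUMNS, "I_X", "I_Y", "status"),
    tolower(c(BIOMETRY_COLUMNS, "I_X", "I_Y", "status")))
  hit <- lut[tolower(names(raw))]
  names(raw)[!is.na(hit)] <- hit[!is.na(hit)]
  miss <- setdiff(BIOMETRY_COLUMNS, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!is.null(exclude_status) && "status" %in% names(raw)) {
    pat <- paste(tolower(exclude_status), collapse = "|")
    drop <- grepl(pat, tolower(raw$status))
    if (any(drop))
      message("excluded ", sum(drop), " of ", nrow(raw),
              " rows by status (", paste(unique(raw$status[drop]),
                                         collapse = ", "), ")")
    raw <- raw[!drop, , drop = FALSE]
  }
  if (!nrow(raw)) stop("no rows left after filtering", call. = FALSE)
  # unit plausibility: radii and depths in mm, not metres or dioptres
  if (any(raw$Ra > 20 | raw$Ra < 4, na.rm = TRUE))
    stop("Ra outside 4-20 mm; check units", call. = FALSE)
  inc <- !stats::complete.cases(raw[BIOMETRY_COLUMNS])
  if (any(inc)) {
    message("excluded ", sum(inc), " incomplete row(s)")
    raw <- raw[!inc, , drop = FALSE]
  }
  bad <- validate_biometry(raw)
  if (length(bad))
    stop("invalid rows: ", paste(bad, collapse = "; "), call. = FALSE)
  if (normalise) raw <- flip_to_left_eye(raw)
  raw
}

#' Write a biometry (or results) table as CSV
#'
#' @param x data.frame.
#' @param path output file.
#' @param sep,dec dialect, as in [read_biometry_csv()].
#' @export
write_biometry_csv <- function(x, path, sep = ",",
                               dec = if (sep == ";") "," else ".") {
  utils::write.table(x, path, sep = sep, dec = dec, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ---- translation model JSON --------------------------------------------------

#' Serialise a translation model to JSON
#'
#' Schema: `regressors`, `responses`, `forward` (2 x p+1), `reverse`,
#' `masks`, `provenance`. Coefficient matrices are stored at full
#' precision.
#'
#' @param model `cw_translation`.
#' @param path output file.
#' @param provenance optional named list recorded verbatim.
#' @export
write_translation_json <- function(model, path, provenance = NULL) {
  fw <- model$forward
  obj <- list(
    regressors = colnames(fw)[-1],
    responses = rownames(fw),
    forward = unclass(fw),
    reverse = unclass(model$reverse),
    masks = lapply(model$masks, function(m)
      stats::setNames(as.list(as.logical(m)), names(m))),
    provenance = provenance %||% list(package = "cwchord",
                                      version = as.character(
                                        utils::packageVersion("cwchord"))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a translation model from JSON
#'
#' Accepts files written by [write_translation_json()] as well as the
#' bundled reference fixture; if the file stores only the forward matrix
#' the reverse is derived by [invert_translation()].
#'
#' @param path JSON file.
#' @return `cw_translation` object (diagnostics `NULL` unless stored).
#' @export
read_translation_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  regs <- obj$regressors
  fw <- matrix(as.numeric(obj$forward), nrow = 2, byrow = FALSE)
  if (!is.null(dim(obj$forward))) fw <- obj$forward
  dimnames(fw) <- list(obj$responses %||% CW_CHORD, c("(Intercept)", regs))
  rv <- if (!is.null(obj$reverse)) {
    m <- obj$reverse
    dimnames(m) <- list(CW_ANGLES,
                        c("(Intercept)", setdiff(regs, CW_ANGLES), CW_CHORD))
    m
  } else invert_translation(fw)
  masks <- if (!is.null(obj$masks)) {
    lapply(obj$masks, function(m) unlist(m))
  } else {
    lapply(stats::setNames(rownames(fw), rownames(fw)),
           function(r) fw[r, -1] != 0)
  }
  structure(list(forward = fw, reverse = rv, masks = masks,
                 diagnostics = NULL, fitted = NULL, residuals = NULL,
                 n = obj$provenance$n %||% NA_integer_,
                 call = NULL, provenance = obj$provenance),
            class = "cw_translation")
}
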