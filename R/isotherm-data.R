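#' Titration datasets: one binding isotherm with film metadata
#'
#' An `isotherm_dataset` holds one NTR titration curve measured on an
#' FG-domain film: the solution concentration grid `c_NTR` (uM), the bound
#' areal density `gamma_NTR` (pmol/cm2), optionally the concomitant film
#' thickness (nm) and measurement errors, together with the FG-domain type,
#' the NTR type and the film grafting density `gamma_FG` (pmol/cm2). Records
#' are stored sorted by concentration.
#'
#' @param fg_domain one of `"Nsp1"`, `"Nup98-glyco"`, `"reg-FSFG"`.
#' @param ntr one of `"NTF2"`, `"Impb"`.
#' @param gamma_FG grafting density of the film, pmol/cm2 (> 0).
#' @param c_NTR solution concentrations, uM (>= 0).
#' @param gamma_NTR bound areal densities, pmol/cm2 (>= 0).
#' @param thickness film thickness, nm (>= 0), or `NULL`/`NA` when not
#'   recorded alongside the isotherm.
#' @param gamma_err,thickness_err optional measurement errors.
#' @param full_range whether the curve covers the 0.05--10 uM fitting window;
#'   inferred from the concentration grid when `NULL`.
#' @return an object of class `isotherm_dataset`.
#' @export
isotherm_dataset <- function(fg_domain, ntr, gamma_FG, c_NTR, gamma_NTR,
                             thickness = NULL, gamma_err = NULL,
                             thickness_err = NULL, full_range = NULL) {
  fg_domain <- match.arg(fg_domain, fg_domain_names())
  ntr <- match.arg(ntr, ntr_names())
  if (!is.finite(gamma_FG) || gamma_FG <= 0)
    stop("`gamma_FG` must be positive", call. = FALSE)
  n <- length(c_NTR)
  if (length(gamma_NTR) != n)
    stop("`c_NTR` and `gamma_NTR` must have equal length", call. = FALSE)
  bad <- which(!is.finite(c_NTR) | c_NTR < 0)
  if (length(bad))
    stop(sprintf("negative or non-finite c_NTR at row %d", bad[1L]),
         call. = FALSE)
  if (any(!is.finite(gamma_NTR) | gamma_NTR < 0))
    stop("`gamma_NTR` must be finite and non-negative", call. = FALSE)
  expand <- function(x) {
    if (is.null(x)) return(rep(NA_real_, n))
    if (length(x) != n) stop("column length mismatch", call. = FALSE)
    as.numeric(x)
  }
  thickness <- expand(thickness)
  if (any(thickness < 0, na.rm = TRUE))
    stop("`thickness` must be non-negative where present", call. = FALSE)
  records <- data.frame(
    c_NTR = as.numeric(c_NTR), gamma_NTR = as.numeric(gamma_NTR),
    gamma_err = expand(gamma_err), thickness = thickness,
    thickness_err = expand(thickness_err)
  )
  records <- records[order(records$c_NTR), , drop = FALSE]
  rownames(records) <- NULL
  if (is.null(full_range))
    full_range <- n >= 4 && min(records$c_NTR) <= 0.05 &&
      max(records$c_NTR) >= 10
  structure(
    list(fg_domain = fg_domain, ntr = ntr, gamma_FG = gamma_FG,
         records = records, full_range = isTRUE(full_range)),
    class = "isotherm_dataset"
  )
}

fg_domain_names <- function() c("Nsp1", "Nup98-glyco", "reg-FSFG")
ntr_names <- function() c("NTF2", "Impb")

#' @export
print.isotherm_dataset <- function(x, ...) {
  cat(sprintf(
    "<isotherm_dataset> %s / %s at %.3g pmol/cm2, %d records (%s range)\n",
    x$ntr, x$fg_domain, x$gamma_FG, nrow(x$records),
    if (x$full_range) "full" else "partial"))
  invisible(x)
}

.meta_cols <- c("dataset", "fg_domain", "ntr", "gamma_FG_pmol_cm2",
                "full_range")
.data_cols <- c("c_NTR_uM", "Gamma_NTR_pmol_cm2", "Gamma_NTR_pmol_cm2_err",
                "thickness_nm", "thickness_nm_err")

fmt_num <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.15g", x))
  out
}

#' Read and write sectioned isotherm tables
#'
#' Titration curves are exchanged as a sectioned CSV: one block per dataset,
#' blocks separated by a blank line. Each block carries a two-line metadata
#' header (`dataset,fg_domain,ntr,gamma_FG_pmol_cm2,full_range`) followed by a
#' per-record table with columns `c_NTR_uM`, `Gamma_NTR_pmol_cm2`,
#' `thickness_nm` and optional `*_err` columns. `write_isotherm_tables()`
#' emits a canonical formatting for which the two functions are exact
#' inverses.
#'
#' @param path file path.
#' @param datasets a list of [isotherm_dataset()] objects.
#' @return `read_isotherm_tables()` returns a list of `isotherm_dataset`;
#'   `write_isotherm_tables()` returns `path` invisibly.
#' @export
read_isotherm_tables <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  # strip trailing blank lines, split blocks on blank lines
  blocks <- split(lines, cumsum(lines == ""))
  blocks <- lapply(blocks, function(b) b[b != ""])
  blocks <- Filter(length, blocks)
  lapply(blocks, parse_isotherm_block)
}

parse_isotherm_block <- function(b) {
  if (length(b) < 4L) stop("malformed isotherm block", call. = FALSE)
  meta_hdr <- strsplit(b[1L], ",", fixed = TRUE)[[1L]]
  for (col in c("fg_domain", "ntr", "gamma_FG_pmol_cm2"))
    if (!col %in% meta_hdr)
      stop(sprintf("missing mandatory metadata column '%s'", col),
           call. = FALSE)
  meta <- setNames(strsplit(b[2L], ",", fixed = TRUE)[[1L]], meta_hdr)
  data_hdr <- strsplit(b[3L], ",", fixed = TRUE)[[1L]]
  for (col in c("c_NTR_uM", "Gamma_NTR_pmol_cm2"))
    if (!col %in% data_hdr)
      stop(sprintf("missing mandatory data column '%s'", col), call. = FALSE)
  tab <- read.csv(text = paste(c(b[3L], b[-(1:3)]), collapse = "\n"),
                  colClasses = "numeric")
  pick <- function(col) if (col %in% names(tab)) tab[[col]] else NULL
  isotherm_dataset(
    fg_domain = unname(meta[["fg_domain"]]),
    ntr = unname(meta[["ntr"]]),
    gamma_FG = as.numeric(meta[["gamma_FG_pmol_cm2"]]),
    c_NTR = tab$c_NTR_uM,
    gamma_NTR = tab$Gamma_NTR_pmol_cm2,
    gamma_err = pick("Gamma_NTR_pmol_cm2_err"),
    thickness = pick("thickness_nm"),
    thickness_err = pick("thickness_nm_err"),
    full_range = if ("full_range" %in% names(meta))
      as.logical(meta[["full_range"]]) else NULL
  )
}

#' @rdname read_isotherm_tables
#' @export
write_isotherm_tables <- function(datasets, path) {
  if (inherits(datasets, "isotherm_dataset")) datasets <- list(datasets)
  blocks <- vapply(seq_along(datasets), function(i) {
    ds <- datasets[[i]]
    stopifnot(inherits(ds, "isotherm_dataset"))
    rec <- ds$records
    cols <- c("c_NTR_uM", "Gamma_NTR_pmol_cm2")
    vals <- list(fmt_num(rec$c_NTR), fmt_num(rec$gamma_NTR))
    if (any(!is.na(rec$gamma_err))) {
      cols <- c(cols, "Gamma_NTR_pmol_cm2_err")
      vals <- c(vals, list(fmt_num(rec$gamma_err)))
    }
    if (any(!is.na(rec$thickness))) {
      cols <- c(cols, "thickness_nm")
      vals <- c(vals, list(fmt_num(rec$thickness)))
      if (any(!is.na(rec$thickness_err))) {
        cols <- c(cols, "thickness_nm_err")
        vals <- c(vals, list(fmt_num(rec$thickness_err)))
      }
    }
    rows <- do.call(paste, c(vals, sep = ","))
    paste(c(
      paste(.meta_cols, collapse = ","),
      sprintf("%d,%s,%s,%s,%s", i, ds$fg_domain, ds$ntr,
              fmt_num(ds$gamma_FG), ds$full_range),
      paste(cols, collapse = ","),
      rows
    ), collapse = "\n")
  }, character(1L))
  writeLines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}
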