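#' Computed LogP values for the 26 ipsapirone derivatives
#'
#' Loads the bundled table of computed octanol--water partition coefficients
#' for a library of 26 ipsapirone derivatives, as obtained from ten
#' prediction algorithms (AlvaDesc: MLogP, ALogP, LogP99 and a consensus;
#' Chemicalize; SwissADME: iLogP, XLogP3, WLogP, Silicos-IT and a consensus),
#' together with the experimentally derived CHI LogP (the chromatographic
#' hydrophobicity index measured on the nonionized form at pH 10.6 and
#' converted to the LogP scale via \code{0.054 * CHI - 1.467}).
#'
#' Values are stored verbatim to the two decimals at which they were
#' measured/reported; the loader performs an integrity check and fails,
#' naming the offending cell, if the file has been corrupted.
#'
#' @return A data frame with 26 rows and columns \code{compound_id}, the ten
#'   computed-LogP scales (see \code{\link{logp_scales}}), and
#'   \code{CHI_LogP}.
#' @seealso [ipsapirone_chromatography()], [verify_integrity()]
#' @export
#' @examples
#' t1 <- ipsapirone_logp()
#' t1$MLogP[1]
ipsapirone_logp <- function() {
  path <- system.file("extdata", "ipsapirone_logp.csv", package = "lipochrom",
                      mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE)
  expected <- c("compound_id", logp_scales(), "CHI_LogP")
  if (!identical(names(d), expected))
    stop("corrupt fixture 'ipsapirone_logp.csv': columns are not the ",
         "expected set (", paste(setdiff(expected, names(d)), collapse = ", "),
         " missing)")
  check_fixture_cells(d, "ipsapirone_logp.csv", n_rows = 26L)
  d
}

#' Chromatographic and biochromatographic indices for the ipsapirone library
#'
#' Loads the bundled table of fast-gradient chromatographic measurements for
#' the 26 ipsapirone derivatives: CHI on a C18 phase at pH 2.6, 7.4 and
#' 10.6, CHI_IAM on an immobilized-artificial-membrane (phosphatidylcholine)
#' phase at pH 7.4, and human serum albumin binding expressed both as
#' \code{logK_HSA} and as percent bound (\code{pct_HSA}).
#'
#' Compound 18's percent-HSA cell is censored (recorded as ">99.80"): its
#' logK_HSA of 2.27 maps above the invertible range of the percent scale.
#' The loader exposes this as \code{pct_HSA = 99.80} with
#' \code{pct_HSA_censored = TRUE}.
#'
#' @return A data frame with 26 rows and columns \code{compound_id},
#'   \code{CHI_pH2.6}, \code{CHI_pH7.4}, \code{CHI_pH10.6}, \code{CHI_IAM},
#'   \code{logK_HSA}, \code{pct_HSA} (numeric) and \code{pct_HSA_censored}
#'   (logical).
#' @seealso [ipsapirone_logp()], [pct_hsa_to_logk()]
#' @export
ipsapirone_chromatography <- function() {
  path <- system.file("extdata", "ipsapirone_chromatography.csv",
                      package = "lipochrom", mustWork = TRUE)
  d <- utils::read.csv(path, check.names = FALSE,
                       colClasses = c(pct_HSA = "character"))
  expected <- c("compound_id", "CHI_pH2.6", "CHI_pH7.4", "CHI_pH10.6",
                "CHI_IAM", "logK_HSA", "pct_HSA")
  if (!identical(names(d), expected))
    stop("corrupt fixture 'ipsapirone_chromatography.csv': unexpected columns")
  censored <- grepl("^>", d$pct_HSA)
  d$pct_HSA_censored <- censored
  d$pct_HSA <- as.numeric(sub("^>", "", d$pct_HSA))
  check_fixture_cells(d[setdiff(names(d), "pct_HSA_censored")],
                      "ipsapirone_chromatography.csv", n_rows = 26L)
  d
}

#' The ten computed-LogP scale names
#'
#' @return Character vector of the computed lipophilicity scale names, in
#'   fixture column order.
#' @export
logp_scales <- function() {
  c("MLogP", "ALogP", "LogP99", "LogPcons_AlvaDesc", "LogP_Chemicalize",
    "iLogP", "XLogP3", "WLogP", "SilicosIT", "LogPcons_SwissADME")
}

#' Combined index table for the ipsapirone library
#'
#' Joins the computed-LogP table with the experimental indices into a single
#' compounds-by-indices table for scale-comparison chemometrics. Column
#' origin (computed vs experimental) is recorded in the
#' \code{"origin"} attribute.
#'
#' @param experimental which experimental columns to append.
#' @return A data frame of 26 compounds by 13 index columns (default), with
#'   attribute \code{origin}: \code{"computed"} or \code{"experimental"}
#'   per index column.
#' @export
ipsapirone_indices <- function(experimental = c("CHI_LogP", "CHI_IAM",
                                                "logK_HSA")) {
  t1 <- ipsapirone_logp()
  t3 <- ipsapirone_chromatography()
  stopifnot(identical(t1$compound_id, t3$compound_id))
  out <- t1[c("compound_id", logp_scales())]
  for (col in experimental)
    out[[col]] <- if (col %in% names(t1)) t1[[col]] else t3[[col]]
  attr(out, "origin") <- c(rep("computed", length(logp_scales())),
                           rep("experimental", length(experimental)))
  names(attr(out, "origin")) <- c(logp_scales(), experimental)
  out
}

#' Cross-table integrity check: CHI LogP consistency
#'
#' Recomputes CHI LogP from the pH-10.6 CHI column of the chromatography
#' table via the linear conversion \code{0.054 * CHI - 1.467} (rounded
#' half-away-from-zero to 2 decimals) and compares it with the CHI LogP
#' column of the computed-LogP table, row by row.
#'
#' @param logp table from [ipsapirone_logp()] (or a compatible data frame).
#' @param chrom table from [ipsapirone_chromatography()].
#' @return A data frame with one row per compound: \code{compound_id},
#'   \code{chi_basic}, \code{chi_logp_printed}, \code{chi_logp_recomputed},
#'   \code{pass}.
#' @export
#' @examples
#' rep <- verify_integrity()
#' all(rep$pass)
verify_integrity <- function(logp = ipsapirone_logp(),
                             chrom = ipsapirone_chromatography()) {
  stopifnot(identical(logp$compound_id, chrom$compound_id))
  recomputed <- chi_to_chilogp(chrom$CHI_pH10.6, round = TRUE)
  data.frame(compound_id = logp$compound_id,
             chi_basic = chrom$CHI_pH10.6,
             chi_logp_printed = logp$CHI_LogP,
             chi_logp_recomputed = recomputed,
             pass = recomputed == logp$CHI_LogP)
}

# Fail loudly, naming the first offending cell, if a fixture carries
# non-finite or missing values or the wrong row count.
check_fixture_cells <- function(d, file, n_rows) {
  if (nrow(d) != n_rows)
    stop("corrupt fixture '", file, "': expected ", n_rows, " rows, got ",
         nrow(d))
  for (col in names(d)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(d[[col]]))))
    if (length(bad))
      stop("corrupt fixture '", file, "': non-numeric value in column '",
           col, "', row ", bad[1])
  }
  invisible(TRUE)
}
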