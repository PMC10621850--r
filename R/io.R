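#' Read a censored observation file
#'
#' Two plain-text dialects are accepted. The line dialect has one observation
#' per line: a numeric literal for a quantified value, or \code{"<c"} for an
#' observation censored at LLOQ \code{c}; lines starting with \code{#} are
#' comments. The CSV dialect has columns \code{status} (\code{quantified} or
#' \code{censored}) and \code{value}, where censored rows carry the LLOQ in
#' the value column. The format is detected from the header unless forced.
#'
#' For \code{family = "poisson"} a censored token \code{"<v"} is an exclusive
#' bound on a count, so the model limit is \eqn{c = v - 1} (censored means
#' \eqn{z \le c}); the reported bound \eqn{v} is retained for half-LLOQ
#' imputation. For the continuous families reported and model limits agree.
#'
#' @param file path to the observation file, or a connection.
#' @param family distribution family the data will be analysed under;
#'   controls the discrete limit convention. \code{"none"} (default) treats
#'   limits as continuous.
#' @param format \code{"auto"}, \code{"lines"} or \code{"csv"}.
#' @return A \code{\link{censored_sample}} with identical limits aggregated
#'   and limits sorted ascending.
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "<5.0", "6.3", "5.9"), f)
#' read_censored(f)
#' @export
read_censored <- function(file, family = c("none", "normal", "exponential", "poisson"),
                          format = c("auto", "lines", "csv")) {
  family <- match.arg(family)
  format <- match.arg(format)
  lines <- readLines(file, warn = FALSE)
  parse_censored(lines, family = family, format = format)
}

#' Parse censored observation records from text lines
#'
#' Workhorse behind \code{\link{read_censored}}; see there for the dialects.
#'
#' @param lines character vector of raw lines.
#' @inheritParams read_censored
#' @return A \code{\link{censored_sample}}.
#' @export
parse_censored <- function(lines, family = c("none", "normal", "exponential", "poisson"),
                           format = c("auto", "lines", "csv")) {
  family <- match.arg(family)
  format <- match.arg(format)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  body <- trimws(lines[keep])
  if (length(body) == 0) stop("no observations found")
  if (format == "auto") {
    format <- if (grepl("^status\\s*,\\s*value$", body[1], ignore.case = TRUE))
      "csv" else "lines"
  }
  if (format == "csv") {
    hdr <- strsplit(tolower(body[1]), "\\s*,\\s*")[[1]]
    if (!identical(hdr, c("status", "value")))
      stop("CSV dialect requires header 'status,value'")
    rows <- body[-1]; rowno <- idx[-1]
    parts <- strsplit(rows, "\\s*,\\s*")
    bad <- lengths(parts) != 2
    if (any(bad))
      stop(sprintf("malformed CSV record at line %d: '%s'",
                   rowno[which(bad)[1]], rows[which(bad)[1]]))
    status <- tolower(vapply(parts, `[[`, "", 1))
    if (!all(status %in% c("quantified", "censored")))
      stop(sprintf("unknown status at line %d: '%s'",
                   rowno[which(!status %in% c("quantified", "censored"))[1]],
                   status[which(!status %in% c("quantified", "censored"))[1]]))
    value <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
    if (anyNA(value))
      stop(sprintf("malformed numeric value at line %d", rowno[which(is.na(value))[1]]))
    quantified <- value[status == "quantified"]
    printed <- value[status == "censored"]
  } else {
    cens <- startsWith(body, "<")
    tok <- ifelse(cens, substring(body, 2), body)
    value <- suppressWarnings(as.numeric(tok))
    if (anyNA(value))
      stop(sprintf("malformed token at line %d: '%s'",
                   idx[which(is.na(value))[1]], body[which(is.na(value))[1]]))
    quantified <- value[!cens]
    printed <- value[cens]
  }
  if (any(quantified < 0) || any(printed <= 0))
    stop("negative observations and limits '<c' with c <= 0 are not valid")
  tab <- if (length(printed)) table(printed) else NULL
  printed_u <- if (length(printed)) as.numeric(names(tab)) else numeric()
  counts <- if (length(printed)) as.integer(tab) else integer()
  o <- order(printed_u)
  printed_u <- printed_u[o]; counts <- counts[o]
  if (family == "poisson") {
    if (any(printed_u != floor(printed_u)))
      stop("Poisson limits must be integers")
    if (length(quantified) && any(quantified != floor(quantified)))
      stop("Poisson observations must be non-negative integers")
    model <- printed_u - 1
  } else {
    model <- printed_u
  }
  censored_sample(quantified, limits = model, counts = counts,
                  printed = printed_u)
}

#' Write a censored sample to a text file
#'
#' Inverse of \code{\link{read_censored}}: writing then re-reading (with the
#' same \code{family}) reproduces the quantified values and the
#' (limit, count) pairs with non-zero counts exactly. Censored records are
#' written with their reported bound, so the discrete limit convention
#' round-trips.
#'
#' @param x a \code{\link{censored_sample}}.
#' @param file output path or connection.
#' @param format \code{"lines"} or \code{"csv"}.
#' @return \code{file}, invisibly.
#' @export
write_censored <- function(x, file, format = c("lines", "csv")) {
  stopifnot(inherits(x, "censored_sample"))
  format <- match.arg(format)
  q <- format(x$quantified, digits = 17, trim = TRUE, scientific = FALSE)
  p <- format(rep(x$printed, x$counts), digits = 17, trim = TRUE,
              scientific = FALSE)
  out <- if (format == "csv") {
    c("status,value",
      if (length(p)) paste0("censored,", p),
      if (length(q)) paste0("quantified,", q))
  } else {
    c(if (length(p)) paste0("<", p), q)
  }
  writeLines(out, file)
  invisible(file)
}

#' Path to a bundled use-case dataset
#'
#' Three small clinical-chemistry datasets of 42 measurements each, taken
#' from a cohort of pharmaceutical-company employees, ship with the package:
#' uric acid (mg/dl, analysed as normal, LLOQs 5.0 and 5.5), ferritin
#' (ng/ml, exponential, LLOQs 80 and 100) and eosinophil counts (Poisson,
#' reported bounds "<3" and "<4").
#'
#' @param name \code{"uric_acid"}, \code{"ferritin"} or \code{"eosin"}.
#' @return path to the installed fixture file.
#' @export
usecase_path <- function(name = c("uric_acid", "ferritin", "eosin")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".txt"), package = "lloqci",
              mustWork = TRUE)
}

#' Family assumed for a bundled use-case dataset
#' @inheritParams usecase_path
#' @return character scalar.
#' @export
usecase_family <- function(name = c("uric_acid", "ferritin", "eosin")) {
  name <- match.arg(name)
  c(uric_acid = "normal", ferritin = "exponential", eosin = "poisson")[[name]]
}
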