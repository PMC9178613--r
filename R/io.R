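.TEMP_ALIASES <- list(
  tfn = c("t_fn", "tfn"),
  kelvin = c("t_k", "tk", "kelvin", "temp_k"),
  celsius = c("t_c", "tc", "celsius", "t_degc", "deg_c")
)

#' Read a melting diagram from delimited text
#'
#' Reads a CSV or TSV file (separator auto-detected from the header line, or
#' given explicitly) with a header naming one temperature column -- `T_fn`,
#' `T_K` or `t_C` -- and a mobile-fraction column `n`.  Kelvin or Celsius
#' temperatures are converted to the normalized fundamental scale.  A file
#' whose header matches more than one temperature alias is rejected rather
#' than guessed at.
#'
#' @param path input file.
#' @param sep field separator; `NULL` auto-detects `","` vs tab.
#' @param temp_col explicit temperature column name, overriding detection.
#' @param sample optional [sample_info()] attached to the series.
#' @param const a [scale_constants()] object.
#' @return An [md_series()] with `kind = "measured"`, sorted by `T_fn`.
#' @export
read_md <- function(path, sep = NULL, temp_col = NULL, sample = NULL,
                    const = scale_constants()) {
  if (!file.exists(path)) stop("melting-diagram file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  nms <- tolower(trimws(names(df)))
  if (is.null(temp_col)) {
    hits <- lapply(.TEMP_ALIASES, function(al) which(nms %in% al))
    found <- names(.TEMP_ALIASES)[vapply(hits, length, integer(1)) > 0]
    if (length(found) == 0L)
      stop("no temperature column found (expected one of T_fn, T_K, t_C)")
    if (length(found) > 1L || length(hits[[found]]) > 1L)
      stop("ambiguous temperature columns: ",
           paste(names(df)[unlist(hits)], collapse = ", "),
           "; use `temp_col` to choose")
    scale <- found
    tcol <- hits[[found]]
  } else {
    tcol <- which(names(df) == temp_col)
    if (length(tcol) != 1L) stop("temperature column '", temp_col,
                                 "' not found")
    scale <- names(.TEMP_ALIASES)[vapply(.TEMP_ALIASES, function(al)
      tolower(temp_col) %in% al, logical(1))]
    if (!length(scale)) stop("cannot infer the scale of column '", temp_col,
                             "' (name it T_fn, T_K or t_C)")
  }
  ncol_i <- which(nms %in% c("n", "mobile_fraction"))
  if (length(ncol_i) != 1L) stop("need exactly one mobile-fraction column 'n'")
  tv <- df[[tcol]]
  tfn <- switch(scale,
                tfn = tv,
                kelvin = tfn_from_kelvin(tv, const),
                celsius = tfn_from_celsius(tv, const))
  o <- order(tfn)
  md_series(tfn[o], df[[ncol_i]][o], sample = sample, kind = "measured")
}

#' Write a melting diagram to delimited text
#'
#' Emits the same format [read_md()] accepts (columns `T_fn`, `n`), so that
#' write/read round-trips are lossless.
#'
#' @param md an [md_series()].
#' @param path output file.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_md <- function(md, path, sep = ",") {
  stopifnot(inherits(md, "md_series"))
  utils::write.table(data.frame(T_fn = md$T_fn, n = md$n), path,
                     sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parenthesis last-digit uncertainty notation
#'
#' Parameter tables in this field quote uncertainties as errors in the last
#' printed digit: `"0.0156(2)"` means 0.0156 with a standard uncertainty of
#' 0.0002.  `parse_paren()` reads that notation, `format_paren()` emits it.
#'
#' @param x a string like `"0.0156(2)"` (plain decimal, no exponent), or for
#'   `format_paren()` a numeric value.
#' @param err for `format_paren()`: the uncertainty of `x`.
#' @return `parse_paren()`: named numeric vector `c(value=, error=)`;
#'   `format_paren()`: a string.
#' @examples
#' parse_paren("0.824(3)")     # value 0.824, error 0.003
#' format_paren(0.6875, 0.02)  # "0.69(2)"
#' @export
parse_paren <- function(x) {
  pat <- "^\\s*(-?[0-9]*\\.?[0-9]+)\\(([0-9]+)\\)(?:[eE]([+-]?[0-9]+))?\\s*$"
  m <- regmatches(x, regexec(pat, x))[[1]]
  if (length(m) != 4L) {
    v <- suppressWarnings(as.numeric(x))
    if (is.na(v)) stop("cannot parse '", x, "' as value(error)")
    return(c(value = v, error = NA_real_))
  }
  val <- as.numeric(m[2])
  dec <- if (grepl("\\.", m[2])) nchar(sub("^[^.]*\\.", "", m[2])) else 0L
  ex <- if (nzchar(m[4])) as.numeric(m[4]) else 0
  c(value = val * 10^ex, error = as.numeric(m[3]) * 10^(ex - dec))
}

#' @rdname parse_paren
#' @export
format_paren <- function(x, err) {
  if (!is.finite(err) || err <= 0) return(format(x))
  dec <- -floor(log10(err))
  last <- round(err * 10^dec)
  if (last >= 10) { dec <- dec - 1L; last <- round(err * 10^dec) }
  if (dec >= 0)
    sprintf("%.*f(%d)", dec, round(x, dec), last)
  else  # uncertainty of 10 or more: quote a power of ten, e.g. "8(1)e2"
    sprintf("%.0f(%d)e%d", x / 10^(-dec), last, -dec)
}

#' Write a full melting-diagram fit report
#'
#' Writes the fitted parameter table (JSON and CSV), the hydration points at
#' the breakpoints and at `T_fn = 1` (CSV), and the heterogeneity report
#' (JSON) into a directory.
#'
#' @param fit an [md_params()] object.
#' @param dir output directory (created if needed).
#' @param sample optional [sample_info()]; enables the hydration table and
#'   the hydration columns of the heterogeneity report.
#' @param classification optional label from [md_classify()].
#' @param const a [scale_constants()] object.
#' @return Named character vector of the files written, invisibly.
#' @export
write_fit_report <- function(fit, dir, sample = NULL, classification = NULL,
                             const = scale_constants()) {
  stopifnot(inherits(fit, "md_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- as.data.frame(fit)
  tab$printed <- mapply(format_paren, tab$value,
                        ifelse(is.na(tab$se), -1, tab$se))
  files <- c(params_csv = file.path(dir, "params.csv"),
             params_json = file.path(dir, "params.json"),
             het_json = file.path(dir, "heterogeneity.json"))
  utils::write.csv(tab, files["params_csv"], row.names = FALSE)
  pj <- list(variant = fit$variant,
             parameters = stats::setNames(as.list(tab$value), tab$parameter),
             se = stats::setNames(as.list(tab$se), tab$parameter),
             rss = fit$rss, nobs = fit$nobs)
  if (!is.null(classification)) pj$classification <- as.character(classification)
  jsonlite::write_json(pj, files["params_json"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  het <- het_report(fit, sample = sample, const = const)
  jsonlite::write_json(as.data.frame(het), files["het_json"],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(sample)) {
    tfns <- c(T_fn0 = fit$T_fn0, T_fn1 = fit$T_fn1, T_fn2 = fit$T_fn2,
              melt = 1)
    hyd <- hydration_from_n(md_evaluate(fit, tfns), sample, tfn = tfns,
                            const = const)
    hyd <- cbind(state = names(tfns), hyd)
    files["hydration_csv"] <- file.path(dir, "hydration.csv")
    utils::write.csv(hyd, files["hydration_csv"], row.names = FALSE)
  }
  invisible(files)
}
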