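#' Heterogeneity statistics of the water-binding barrier distribution
#'
#' From a fitted melting curve, derives the statistics that summarise how
#' homogeneous or heterogeneous the potential-barrier distribution of the
#' protein-water bonds is:
#' \describe{
#'   \item{`n_ho`}{mobile water fraction bound homogeneously; equals the
#'     plateau amplitude `A`.}
#'   \item{`n_he`}{heterogeneously bound fraction, `n(T_fn = 1) - n_ho`.}
#'   \item{`HeR`}{heterogeneity ratio of the barrier distribution,
#'     `(1 - T_fn1) / (1 - T_fn0)`; depends only on the breakpoints.}
#'   \item{`HeR_n`}{fraction of heterogeneously bound water,
#'     `n_he / (n_ho + n_he)`.}
#'   \item{`HeM`}{rate measure of heterogeneity near 0 degC,
#'     `(B + 2C) / (1 - T_fn1)`.}
#'   \item{`homog_pct`}{percentage with homogeneous barrier distribution,
#'     `100 (1 - HeR)`.}
#' }
#' For the extended variant, `B` in `HeM` is the upper slope `B2` (the slope
#' active approaching `T_fn = 1`) and `T_fn0` is the effective plateau onset;
#' both choices are recorded in the report.
#'
#' @param p an [md_params()] object with `T_fn1 < 1`.
#' @param sample optional [sample_info()]; when given, `n_ho`/`n_he` are also
#'   reported on the hydration (`h_ho`, `h_he`) and per-residue (`naa_ho`,
#'   `naa_he`) scales.
#' @param const a [scale_constants()] object.
#' @return An object of class `"het_report"`: a named list of the statistics
#'   plus bookkeeping fields `variant`, `B_used` and `T_fn0_used`.
#' @examples
#' a30p <- md_params(A = 0.0156, B = 0.24, C = 50,
#'                   T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
#' het_report(a30p)$HeR  # 0.6875
#' @export
het_report <- function(p, sample = NULL, const = scale_constants()) {
  stopifnot(inherits(p, "md_params"))
  if (p$T_fn1 >= 1)
    stop("T_fn1 must be below 1: HeR and HeM divide by (1 - T_fn1)")
  n1 <- md_evaluate(p, 1)
  n_ho <- p$A
  n_he <- n1 - n_ho
  if (n_he < 0) stop("n(T_fn = 1) is below the plateau; invalid fit")
  B_used <- if (p$variant == "extended") p$B2 else p$B
  HeR <- (1 - p$T_fn1) / (1 - p$T_fn0)
  out <- list(
    n_ho = n_ho, n_he = n_he,
    HeR = HeR,
    HeR_n = if (n1 > 0) n_he / n1 else 0,
    HeM = (B_used + 2 * p$C) / (1 - p$T_fn1),
    homog_pct = 100 * (1 - HeR),
    variant = p$variant, B_used = B_used, T_fn0_used = p$T_fn0
  )
  if (!is.null(sample)) {
    hp <- hydration_from_n(c(n_ho, n_he), sample, const = const)
    out$naa_ho <- hp$naa[1]; out$naa_he <- hp$naa[2]
    out$h_ho <- hp$h[1]; out$h_he <- hp$h[2]
  }
  structure(out, class = "het_report")
}

#' @export
print.het_report <- function(x, ...) {
  cat("Water-binding heterogeneity report (", x$variant, " variant)\n",
      sep = "")
  fmt <- function(lbl, v) cat(sprintf("  %-10s %.4g\n", lbl, v))
  fmt("n_ho", x$n_ho); fmt("n_he", x$n_he)
  if (!is.null(x$naa_ho)) {
    fmt("naa_ho", x$naa_ho); fmt("naa_he", x$naa_he)
    fmt("h_ho", x$h_ho); fmt("h_he", x$h_he)
  }
  fmt("HeR", x$HeR); fmt("HeR_n", x$HeR_n); fmt("HeM", x$HeM)
  cat(sprintf("  %-10s %d%%\n", "homogeneous", round(x$homog_pct)))
  invisible(x)
}

#' @describeIn het_report flatten to a one-row data frame (numeric fields
#'   only; `homog_pct` rounded to integer for reporting).
#' @param x a `het_report`.
#' @param ... unused.
#' @export
as.data.frame.het_report <- function(x, ...) {
  nums <- x[vapply(x, is.numeric, logical(1))]
  df <- as.data.frame(nums)
  df$homog_pct <- round(df$homog_pct)
  df
}
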