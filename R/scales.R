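#' Physical constants for melting-diagram scales
#'
#' The melting-diagram analysis works on the normalized fundamental
#' temperature scale \eqn{T_{fn} = T / 273.15} (so that the melting point of
#' ice maps to 1) and on the potential-barrier scale
#' \eqn{E_a = L_f \cdot T_{fn}}, anchored by the molar heat of fusion of ice
#' \eqn{L_f = 6.01} kJ/mol at 0 degrees Celsius.
#'
#' @param T0 melting point of ice in Kelvin.
#' @param L_f molar heat of fusion of ice, kJ/mol; the potential barrier at
#'   \eqn{T_{fn} = 1}.
#' @param rho_w density of water, g/mL.
#' @param M_r_w molar mass of water, g/mol.
#' @return An object of class `"scale_constants"`: a named list with the four
#'   constants.
#' @examples
#' sc <- scale_constants()
#' ea_from_tfn(1, sc)  # 6.01 kJ/mol at 0 degC
#' @export
scale_constants <- function(T0 = 273.15, L_f = 6.01, rho_w = 1.0,
                            M_r_w = 18.015) {
  if (!all(c(T0, L_f, rho_w, M_r_w) > 0))
    stop("all scale constants must be strictly positive")
  structure(list(T0 = T0, L_f = L_f, rho_w = rho_w, M_r_w = M_r_w),
            class = "scale_constants")
}

#' @export
print.scale_constants <- function(x, ...) {
  cat("Melting-diagram scale constants:\n")
  cat(sprintf("  T0    = %.2f K (melting point of ice)\n", x$T0))
  cat(sprintf("  L_f   = %.2f kJ/mol (heat of fusion of ice)\n", x$L_f))
  cat(sprintf("  rho_w = %.3f g/mL\n", x$rho_w))
  cat(sprintf("  M_r_w = %.3f g/mol\n", x$M_r_w))
  invisible(x)
}

#' Temperature-scale conversions
#'
#' Convert between Kelvin, degrees Celsius, the normalized fundamental
#' temperature `T_fn` and the potential-barrier scale `E_a` (kJ/mol).  All
#' conversions are linear, vectorized and mutually inverse to machine
#' precision.
#'
#' @param T temperature in Kelvin (strictly positive).
#' @param tfn normalized fundamental temperature, `T / 273.15` (strictly
#'   positive).
#' @param t temperature in degrees Celsius (above absolute zero).
#' @param ea potential barrier in kJ/mol (strictly positive).
#' @param const a [scale_constants()] object.
#' @return Numeric vector on the requested scale.
#' @examples
#' tfn_from_kelvin(273.15)        # 1
#' ea_from_tfn(0.824)             # 4.95 kJ/mol, a typical plateau onset
#' celsius_from_tfn(0.879)        # -33.05 degC
#' @name temperature_scales
NULL

#' @rdname temperature_scales
#' @export
tfn_from_kelvin <- function(T, const = scale_constants()) {
  if (any(T <= 0)) stop("temperature in Kelvin must be strictly positive")
  T / const$T0
}

#' @rdname temperature_scales
#' @export
kelvin_from_tfn <- function(tfn, const = scale_constants()) {
  if (any(tfn <= 0)) stop("T_fn must be strictly positive")
  tfn * const$T0
}

#' @rdname temperature_scales
#' @export
tfn_from_celsius <- function(t, const = scale_constants()) {
  tfn_from_kelvin(t + const$T0, const)
}

#' @rdname temperature_scales
#' @export
celsius_from_tfn <- function(tfn, const = scale_constants()) {
  if (any(tfn <= 0)) stop("T_fn must be strictly positive")
  const$T0 * (tfn - 1)
}

#' @rdname temperature_scales
#' @export
ea_from_tfn <- function(tfn, const = scale_constants()) {
  if (any(tfn <= 0)) stop("T_fn must be strictly positive")
  const$L_f * tfn
}

#' @rdname temperature_scales
#' @export
tfn_from_ea <- function(ea, const = scale_constants()) {
  if (any(ea <= 0)) stop("E_a must be strictly positive")
  ea / const$L_f
}

#' Sample metadata for hydration conversions
#'
#' Bundles the protein and the nominal solution concentration.  All
#' conversions between the measured mobile-proton fraction `n` and hydration
#' measures depend on the sample through the water:protein mass ratio and the
#' protein molar mass.
#'
#' @param protein a [protein_info()] object.
#' @param concentration protein concentration in mg per mL of water; must lie
#'   in (0, 1000).
#' @return An object of class `"sample_info"`.
#' @examples
#' p <- protein_info("GGAG", name = "toy")
#' s <- sample_info(p, concentration = 50)
#' mass_ratio(s)  # 20 g water per g protein
#' @export
sample_info <- function(protein, concentration = 50) {
  if (!inherits(protein, "protein_info"))
    stop("`protein` must be a protein_info object")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0 || concentration >= 1000)
    stop("`concentration` must be a single value in (0, 1000) mg/mL")
  structure(list(protein = protein, concentration = concentration),
            class = "sample_info")
}

#' @export
print.sample_info <- function(x, ...) {
  cat(sprintf("Sample: %s at %.1f mg/mL (r = %.3g g water / g protein)\n",
              x$protein$name, x$concentration, mass_ratio(x)))
  invisible(x)
}

#' Water:protein mass ratio of a sample
#'
#' `r = m_water / m_protein = 1000 * rho_w / c` for a concentration `c` in
#' mg protein per mL water.  The protein's own volume is neglected; at the
#' usual 50 mg/mL this correction is below the experimental uncertainty.
#'
#' @inheritParams sample_info
#' @param s a [sample_info()] object.
#' @param const a [scale_constants()] object.
#' @return The dimensionless mass ratio (g water per g protein).
#' @export
mass_ratio <- function(s, const = scale_constants()) {
  if (!inherits(s, "sample_info")) stop("`s` must be a sample_info object")
  1000 * const$rho_w / s$concentration
}

#' Convert a mobile-water fraction to hydration measures
#'
#' Converts the measured fraction of mobile water protons `n` to
#' \describe{
#'   \item{`h`}{hydration in g mobile water per g protein, `h = n * r`;}
#'   \item{`W`}{mobile water molecules per protein molecule,
#'     `W = (n/2) * r * M_r(protein) / M_r(water)` -- the factor 1/2 counts
#'     two protons per water molecule;}
#'   \item{`naa`}{mobile waters per amino-acid residue, `naa = W / a`.}
#' }
#' where `r` is the sample's water:protein mass ratio.  If a temperature
#' coordinate is supplied the point also carries `T_fn`, `E_a` (kJ/mol) and
#' `t` (degC).
#'
#' All quantities are homogeneous of degree 1 in `n`, and `h / naa` is a
#' sample constant.
#'
#' @param n mobile proton fraction(s) in \[0, 1\].
#' @param s a [sample_info()] object (required: conversions are
#'   concentration-dependent).
#' @param tfn optional normalized fundamental temperature(s) of the state,
#'   recycled against `n`.
#' @param const a [scale_constants()] object.
#' @return A data frame of class `"hydration_point"` with columns
#'   `T_fn`, `E_a`, `t`, `n`, `h`, `naa`, `W`.
#' @examples
#' asyn <- read_fasta(system.file("extdata", "alpha_synuclein_wt.fasta",
#'                                package = "hydromelt"))
#' a30p <- sample_info(apply_mutation(asyn, "A30P"), 50)
#' hydration_from_n(0.0156, a30p)  # about a monolayer: h = 0.31, W = 125
#' @export
hydration_from_n <- function(n, s, tfn = NA_real_, const = scale_constants()) {
  if (missing(s) || !inherits(s, "sample_info"))
    stop("a sample_info object is required: hydration depends on concentration")
  if (any(n < 0 | n > 1)) stop("mobile fraction n must lie in [0, 1]")
  k <- max(length(n), length(tfn))
  n <- rep_len(n, k)
  tfn <- rep_len(tfn, k)
  r <- mass_ratio(s, const)
  p <- s$protein
  W <- (n / 2) * r * p$M_r / const$M_r_w
  out <- data.frame(
    T_fn = tfn,
    E_a = ifelse(is.na(tfn), NA_real_, const$L_f * tfn),
    t = ifelse(is.na(tfn), NA_real_, const$T0 * (tfn - 1)),
    n = n,
    h = n * r,
    naa = W / p$a,
    W = W
  )
  class(out) <- c("hydration_point", "data.frame")
  out
}
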