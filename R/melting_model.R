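#' Melting-diagram series
#'
#' An ordered series of (normalized fundamental temperature, mobile water
#' fraction) observations.  The same container holds measured diagrams,
#' model-evaluated curves and differential melting diagrams (where `n` holds
#' `dn/dT_fn`).
#'
#' @param tfn strictly increasing vector of normalized fundamental
#'   temperatures in (0, 1.05].
#' @param n mobile proton fractions (or derivative values for
#'   `kind = "differential"`), non-negative, same length as `tfn`.
#' @param sample optional [sample_info()] metadata.
#' @param kind one of `"measured"`, `"fitted"`, `"differential"`.
#' @return A data frame of class `"md_series"` with columns `T_fn`, `n` and
#'   attributes `sample` and `kind`.
#' @export
md_series <- function(tfn, n, sample = NULL, kind = c("measured", "fitted",
                                                      "differential")) {
  kind <- match.arg(kind)
  if (length(tfn) != length(n)) stop("T_fn and n must have equal length")
  if (length(tfn) < 4L) stop("a melting diagram needs at least 4 points")
  if (any(!is.finite(tfn)) || any(!is.finite(n)))
    stop("non-finite values in melting diagram")
  if (any(diff(tfn) <= 0)) stop("T_fn must be strictly increasing")
  if (any(tfn <= 0) || any(tfn > 1.05))
    stop("T_fn must lie in (0, 1.05]")
  if (any(n < 0)) stop("n must be non-negative")
  if (!is.null(sample) && !inherits(sample, "sample_info"))
    stop("`sample` must be a sample_info object")
  out <- data.frame(T_fn = as.numeric(tfn), n = as.numeric(n))
  attr(out, "sample") <- sample
  attr(out, "kind") <- kind
  class(out) <- c("md_series", "data.frame")
  out
}

#' @export
print.md_series <- function(x, ...) {
  cat(sprintf("Melting diagram (%s): %d points, T_fn in [%.3f, %.3f]\n",
              attr(x, "kind"), nrow(x), min(x$T_fn), max(x$T_fn)))
  NextMethod()
}

#' Piecewise melting-curve parameters
#'
#' Parameters of the segmented melting-curve model.  The **standard** variant
#' is zero below the onset `T_fn0`, a plateau of height `A` on
#' `[T_fn0, T_fn1)`, linear with slope `B` on `[T_fn1, T_fn2)` and gains an
#' additional quadratic term `C * (T_fn - T_fn2)^2` beyond `T_fn2`.  The
#' **extended** variant adds a linear onset ramp from 0 at `T_fn_onset` up to
#' `A` at `T_fn0`, a jump of size `delta` at the plateau end `T_fn1`, and two
#' linear slopes `B1` (below the slope-change point `T_fnx`) and `B2` (above
#' it), joined value-continuously.
#'
#' @param variant `"standard"` or `"extended"`.
#' @param A plateau mobile fraction (>= 0).
#' @param B linear slope (standard variant).
#' @param C quadratic coefficient.
#' @param T_fn0,T_fn1,T_fn2 breakpoints: plateau onset, plateau end,
#'   quadratic onset; must satisfy `T_fn0 < T_fn1 < T_fn2 <= 1`.
#' @param B1,B2 the two slopes of the extended variant (below/above `T_fnx`).
#' @param T_fn_onset first temperature with mobile water (extended variant;
#'   `< T_fn0`).
#' @param T_fnx slope-change point (extended variant; in `(T_fn1, T_fn2)`).
#' @param delta jump in `n` at `T_fn1` (extended variant, >= 0).
#' @param se optional named list/vector of parameter uncertainties.
#' @param rss,nobs optional fit diagnostics (residual sum of squares, number
#'   of observations) attached by [md_fit()].
#' @return An object of class `"md_params"`.
#' @examples
#' p <- md_params(A = 0.0156, B = 0.24, C = 50,
#'                T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
#' md_evaluate(p, 1)  # 0.129
#' @export
md_params <- function(variant = c("standard", "extended"),
                      A, B = NULL, C, T_fn0, T_fn1, T_fn2,
                      B1 = NULL, B2 = NULL, T_fn_onset = NULL, T_fnx = NULL,
                      delta = NULL, se = NULL, rss = NULL, nobs = NULL) {
  variant <- match.arg(variant)
  chk_num <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("`", nm, "` must be a single finite number")
    x
  }
  A <- chk_num(A, "A"); C <- chk_num(C, "C")
  T_fn0 <- chk_num(T_fn0, "T_fn0"); T_fn1 <- chk_num(T_fn1, "T_fn1")
  T_fn2 <- chk_num(T_fn2, "T_fn2")
  amps <- c(A = A, C = C)
  if (variant == "standard") {
    B <- chk_num(B, "B")
    amps <- c(amps, B = B)
    bps <- c(T_fn0 = T_fn0, T_fn1 = T_fn1, T_fn2 = T_fn2)
  } else {
    B1 <- chk_num(B1, "B1"); B2 <- chk_num(B2, "B2")
    T_fn_onset <- chk_num(T_fn_onset, "T_fn_onset")
    T_fnx <- chk_num(T_fnx, "T_fnx")
    delta <- if (is.null(delta)) 0 else chk_num(delta, "delta")
    amps <- c(amps, B1 = B1, B2 = B2, delta = delta)
    bps <- c(T_fn_onset = T_fn_onset, T_fn0 = T_fn0, T_fn1 = T_fn1,
             T_fnx = T_fnx, T_fn2 = T_fn2)
  }
  if (any(amps < 0)) stop("amplitudes (A, B, B1, B2, C, delta) must be >= 0")
  if (any(diff(bps) <= 0) || T_fn2 > 1 + 1e-9)
    stop("breakpoints must be strictly ordered (",
         paste(names(bps), collapse = " < "), " <= 1)")
  structure(list(variant = variant, A = A, B = B, B1 = B1, B2 = B2, C = C,
                 T_fn_onset = T_fn_onset, T_fn0 = T_fn0, T_fn1 = T_fn1,
                 T_fnx = T_fnx, T_fn2 = T_fn2, delta = delta,
                 se = se, rss = rss, nobs = nobs),
            class = "md_params")
}

#' @export
print.md_params <- function(x, digits = 4, ...) {
  cat(sprintf("Piecewise melting-curve parameters (%s variant)\n", x$variant))
  tab <- as.data.frame(x)
  print(tab, row.names = FALSE, digits = digits)
  if (!is.null(x$rss))
    cat(sprintf("RSS = %.3g on %d points\n", x$rss, x$nobs))
  invisible(x)
}

#' @describeIn md_params tabular view: one row per parameter with columns
#'   `parameter`, `value`, `se` (NA where not estimated).
#' @param x an `md_params` object.
#' @param ... unused.
#' @export
as.data.frame.md_params <- function(x, ...) {
  nms <- if (x$variant == "standard")
    c("A", "B", "C", "T_fn0", "T_fn1", "T_fn2")
  else
    c("A", "delta", "B1", "B2", "C", "T_fn_onset", "T_fn0", "T_fn1",
      "T_fnx", "T_fn2")
  vals <- vapply(nms, function(k) x[[k]], numeric(1))
  ses <- rep(NA_real_, length(nms))
  if (!is.null(x$se)) {
    hit <- intersect(names(x$se), nms)
    ses[match(hit, nms)] <- unlist(x$se)[hit]
  }
  data.frame(parameter = nms, value = unname(vals), se = ses)
}

#' Evaluate the piecewise melting-curve model
#'
#' Computes the modelled mobile water fraction at given normalized
#' fundamental temperatures.  The curve is non-decreasing for non-negative
#' amplitudes, and continuous everywhere except (in the extended variant) the
#' jump at `T_fn1`.
#'
#' @param p an [md_params()] object.
#' @param tfn numeric vector of normalized fundamental temperatures.
#' @return Numeric vector of mobile fractions, same length as `tfn`.
#' @export
md_evaluate <- function(p, tfn) {
  if (!inherits(p, "md_params")) stop("`p` must be an md_params object")
  if (p$variant == "standard") {
    n <- numeric(length(tfn))
    on <- tfn >= p$T_fn0
    n[on] <- p$A
    i <- tfn >= p$T_fn1
    n[i] <- p$A + p$B * (tfn[i] - p$T_fn1)
    j <- tfn >= p$T_fn2
    n[j] <- n[j] + p$C * (tfn[j] - p$T_fn2)^2
  } else {
    n <- p$A * pmin(pmax((tfn - p$T_fn_onset) / (p$T_fn0 - p$T_fn_onset), 0), 1)
    i <- tfn >= p$T_fn1
    n[i] <- p$A + p$delta + p$B1 * (pmin(tfn[i], p$T_fnx) - p$T_fn1) +
      p$B2 * pmax(tfn[i] - p$T_fnx, 0) +
      p$C * pmax(tfn[i] - p$T_fn2, 0)^2
  }
  n
}

# ---- internal least-squares machinery -------------------------------------

# Non-negative amplitude solve: ordinary LS, then iteratively clamp the most
# negative coefficient at zero and refit.  Returns coefficients on the full
# column set (clamped entries exactly 0), fitted values, RSS and a flag.
.solve_amps <- function(X, y) {
  k <- ncol(X)
  keep <- rep(TRUE, k)
  clamped <- FALSE
  repeat {
    b <- numeric(k)
    if (any(keep)) {
      fit <- stats::lm.fit(X[, keep, drop = FALSE], y)
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      b[keep] <- cf
    }
    neg <- which(b < -1e-12)
    if (!length(neg)) break
    clamped <- TRUE
    keep[neg[which.min(b[neg])]] <- FALSE
  }
  fitted <- drop(X %*% b)
  list(coef = b, fitted = fitted, rss = sum((y - fitted)^2), clamped = clamped)
}

.basis_standard <- function(tfn, bp) {
  on <- as.numeric(tfn >= bp[1])
  cbind(A = on,
        B = on * pmax(tfn - bp[2], 0),
        C = on * pmax(tfn - bp[3], 0)^2)
}

.basis_extended <- function(tfn, bp) {
  # bp = (onset, T0, T1, Tx, T2)
  cbind(A = pmin(pmax((tfn - bp[1]) / (bp[2] - bp[1]), 0), 1),
        delta = as.numeric(tfn >= bp[3]),
        B1 = pmax(pmin(tfn, bp[4]) - bp[3], 0) * (tfn >= bp[3]),
        B2 = pmax(tfn - bp[4], 0),
        C = pmax(tfn - bp[5], 0)^2)
}

.rss_for_bp <- function(tfn, n, bp, variant) {
  X <- if (variant == "standard") .basis_standard(tfn, bp)
       else .basis_extended(tfn, bp)
  .solve_amps(X, n)$rss
}

# Vectorized profiled grid search for the standard variant.  For each
# (T0, T1) the 3x3 normal equations are solved simultaneously for all T2
# candidates by Cramer's rule; candidates whose unconstrained solution has a
# negative amplitude are re-solved with clamping.  Returns the `top` best
# breakpoint triples (ties resolved toward the smaller T_fn1 by scan order).
.grid_standard <- function(tfn, n, grid, min_seg = 2L, top = 5L) {
  ytot <- sum(n^2)
  res <- list()
  # T0 candidates only matter through the induced on/off partition
  nbelow <- vapply(grid, function(g) sum(tfn < g), integer(1))
  t0_idx <- which(!duplicated(nbelow) & grid <= max(tfn))
  cand <- matrix(numeric(0), ncol = 4)
  for (i0 in t0_idx) {
    T0 <- grid[i0]
    on <- tfn >= T0
    if (sum(on) < 3L * min_seg) next
    t_on <- tfn[on]; y_on <- n[on]
    rss_off <- ytot - sum(y_on^2)
    for (i1 in seq_along(grid)) {
      T1 <- grid[i1]
      if (T1 <= T0) next
      if (sum(t_on < T1) < min_seg) next
      t2s <- grid[grid > T1]
      ok <- vapply(t2s, function(g)
        sum(t_on >= T1 & t_on < g) >= min_seg && sum(t_on >= g) >= min_seg,
        logical(1))
      t2s <- t2s[ok]
      if (!length(t2s)) next
      u <- pmax(t_on - T1, 0)
      Q <- pmax(outer(t_on, t2s, "-"), 0)^2
      S11 <- sum(on); S12 <- sum(u); S22 <- sum(u^2)
      b1 <- sum(y_on); b2 <- sum(y_on * u)
      S13 <- colSums(Q); S23 <- colSums(u * Q); S33 <- colSums(Q^2)
      b3 <- colSums(y_on * Q)
      det <- S11 * (S22 * S33 - S23^2) - S12 * (S12 * S33 - S23 * S13) +
        S13 * (S12 * S23 - S22 * S13)
      bad <- abs(det) < 1e-300
      det[bad] <- 1
      bA <- (b1 * (S22 * S33 - S23^2) - S12 * (b2 * S33 - S23 * b3) +
               S13 * (b2 * S23 - S22 * b3)) / det
      bB <- (S11 * (b2 * S33 - b3 * S23) - b1 * (S12 * S33 - S13 * S23) +
               S13 * (S12 * b3 - b2 * S13)) / det
      bC <- (S11 * (S22 * b3 - S23 * b2) - S12 * (S12 * b3 - S13 * b2) +
               b1 * (S12 * S23 - S22 * S13)) / det
      rss <- sum(y_on^2) + rss_off - (bA * b1 + bB * b2 + bC * b3)
      rss[bad] <- Inf
      neg <- !bad & (bA < -1e-10 | bB < -1e-10 | bC < -1e-10)
      if (any(neg)) {
        for (j in which(neg)) {
          rss[j] <- .rss_for_bp(tfn, n, c(T0, T1, t2s[j]), "standard")
        }
      }
      jbest <- which.min(rss)
      cand <- rbind(cand, c(T0, T1, t2s[jbest], rss[jbest]))
    }
  }
  if (!nrow(cand)) stop("no admissible breakpoint triple on the grid; ",
                        "data may not span enough regimes")
  cand[order(cand[, 4], cand[, 2]), , drop = FALSE][seq_len(min(top, nrow(cand))), ,
                                                    drop = FALSE]
}

# Exact segment-wise polish for noise-free (or nearly so) standard data:
# given a segment assignment, plateau level, line and continuing quadratic
# are solved in closed form and the interior breakpoints recovered from
# continuity.  Returns NULL when the assignment is unusable.
.polish_standard <- function(tfn, n, bp) {
  T0 <- bp[1]
  pl <- tfn >= T0 & tfn < bp[2]
  li <- tfn >= bp[2] & tfn < bp[3]
  qu <- tfn >= bp[3]
  if (sum(pl) < 1L || sum(li) < 2L || sum(qu) < 3L) return(NULL)
  A <- mean(n[pl])
  lf <- stats::lm.fit(cbind(1, tfn[li]), n[li])
  a0 <- lf$coefficients[1]; B <- lf$coefficients[2]
  if (!is.finite(B) || B <= 0) return(NULL)
  T1 <- (A - a0) / B
  r <- n[qu] - (a0 + B * tfn[qu])
  qf <- stats::lm.fit(cbind(1, tfn[qu], tfn[qu]^2), r)
  c2 <- qf$coefficients[3]
  if (!is.finite(c2) || c2 <= 0) return(NULL)
  T2 <- -qf$coefficients[2] / (2 * c2)
  out <- c(T0, T1, T2)
  if (any(!is.finite(out)) || any(diff(out) <= 0) || T2 > max(tfn)) return(NULL)
  out
}

.finalize <- function(tfn, n, bp, variant, warn_clamp = TRUE) {
  X <- if (variant == "standard") .basis_standard(tfn, bp)
       else .basis_extended(tfn, bp)
  sol <- .solve_amps(X, n)
  if (sol$clamped && warn_clamp)
    warning("negative amplitude encountered; clamped at zero and refitted")
  npar <- ncol(X) + length(bp)
  sigma2 <- sol$rss / max(length(n) - npar, 1L)
  se <- tryCatch({
    keep <- sol$coef > 0 | colSums(X != 0) > 0
    V <- sigma2 * chol2inv(chol(crossprod(X[, keep, drop = FALSE])))
    s <- rep(NA_real_, ncol(X)); s[keep] <- sqrt(diag(V))
    stats::setNames(s, colnames(X))
  }, error = function(e) stats::setNames(rep(NA_real_, ncol(X)), colnames(X)))
  cf <- stats::setNames(sol$coef, colnames(X))
  bp <- unname(bp)
  if (variant == "standard") {
    md_params("standard", A = cf[["A"]], B = cf[["B"]], C = cf[["C"]],
              T_fn0 = bp[1], T_fn1 = bp[2], T_fn2 = bp[3],
              se = as.list(se), rss = sol$rss, nobs = length(n))
  } else {
    md_params("extended", A = cf[["A"]], delta = cf[["delta"]],
              B1 = cf[["B1"]], B2 = cf[["B2"]], C = cf[["C"]],
              T_fn_onset = bp[1], T_fn0 = bp[2], T_fn1 = bp[3],
              T_fnx = bp[4], T_fn2 = bp[5],
              se = as.list(se), rss = sol$rss, nobs = length(n))
  }
}

#' Brute-force breakpoint grid fit
#'
#' Fits the standard piecewise melting-curve model with breakpoints
#' restricted to a regular grid; for each admissible ordered triple the
#' amplitude subproblem is solved exactly by linear least squares.  Slower
#' but assumption-free; [md_fit()] must never end up with a larger residual
#' sum of squares than this search on the same data.
#'
#' @param md an [md_series()] (kind `"measured"` or `"fitted"`).
#' @param step breakpoint grid spacing on the `T_fn` axis.
#' @param min_seg minimum number of observations required in each of the
#'   plateau, linear and quadratic segments.
#' @return An `md_params` object (with `rss` and `nobs` filled in).
#' @export
md_fit_grid <- function(md, step = 0.001, min_seg = 2L) {
  stopifnot(inherits(md, "md_series"))
  tfn <- md$T_fn; n <- md$n
  grid <- seq(min(tfn), max(tfn), by = step)
  best <- .grid_standard(tfn, n, grid, min_seg = min_seg, top = 1L)
  .finalize(tfn, n, best[1, 1:3], "standard", warn_clamp = FALSE)
}

#' Fit the piecewise melting-curve model
#'
#' Estimates the segmented melting-curve parameters by profiled least
#' squares: for fixed breakpoints the amplitude subproblem is linear and
#' solved exactly (with non-negativity enforced by clamp-and-refit); the
#' breakpoints are located by a coarse grid search followed by local
#' refinement ([stats::nlminb()]) and, for the standard variant, an exact
#' segment-wise polish that recovers noise-free parameters to machine
#' precision.  Observations below the candidate onset are compared against a
#' zero baseline, which keeps the onset breakpoint identifiable.  The fit is
#' deterministic: no randomness is involved.
#'
#' For the extended variant the onset and slope-change breakpoints are
#' initialized from a standard-variant fit and a coarse scan, then all five
#' breakpoints are refined jointly.
#'
#' @param md an [md_series()] with at least 8 points spanning at least two
#'   regimes of the curve.
#' @param variant `"standard"` or `"extended"`.
#' @param grid_step spacing of the coarse breakpoint grid.
#' @param min_seg minimum observations per segment during the grid stage.
#' @param refine logical; run local refinement after the grid stage.
#' @return An [md_params()] object carrying amplitude standard errors (from
#'   the final linear solve), the residual sum of squares and the number of
#'   observations.
#' @examples
#' truth <- md_params(A = 0.0156, B = 0.24, C = 50,
#'                    T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
#' md <- gen_md(truth, grid = seq(0.80, 1, length.out = 40), sigma = 0)
#' fit <- md_fit(md)
#' fit$rss  # essentially zero
#' @export
md_fit <- function(md, variant = c("standard", "extended"),
                   grid_step = 0.005, min_seg = 2L, refine = TRUE) {
  variant <- match.arg(variant)
  stopifnot(inherits(md, "md_series"))
  tfn <- md$T_fn; n <- md$n
  npar <- if (variant == "standard") 6L else 10L
  if (length(tfn) < max(8L, npar))
    stop("too few points: the ", variant, " variant needs at least ",
         max(8L, npar), " observations")
  if (variant == "standard") .md_fit_standard(tfn, n, grid_step, min_seg, refine)
  else .md_fit_extended(tfn, n, grid_step, min_seg, refine)
}

# The onset breakpoint enters the objective only through the on/off
# partition of the observations (prediction is 0 below it), so RSS is a step
# function of T_fn0 and gradient-based refinement cannot move it.  Given
# (T_fn1, T_fn2), scan all partition classes exactly; report the onset as
# the midpoint of the gap between the last excluded and first included point
# (within which it is not identifiable).
.scan_t0 <- function(tfn, n, T1, T2) {
  cands <- sort(unique(tfn[tfn < T1]))
  if (!length(cands)) cands <- min(tfn)
  rss <- vapply(cands, function(T0)
    .rss_for_bp(tfn, n, c(T0, T1, T2), "standard"), numeric(1))
  T0 <- cands[which.min(rss)]
  below <- tfn[tfn < T0]
  if (length(below)) T0 <- (max(below) + T0) / 2
  T0
}

.md_fit_standard <- function(tfn, n, grid_step, min_seg, refine) {
  grid <- seq(min(tfn), max(tfn), by = grid_step)
  cand <- .grid_standard(tfn, n, grid, min_seg = min_seg, top = 5L)
  bps <- lapply(seq_len(nrow(cand)), function(i) cand[i, 1:3])
  obj <- function(bp) {
    if (bp[1] >= bp[2] - 1e-6 || bp[2] >= bp[3] - 1e-6) return(1e6)
    .rss_for_bp(tfn, n, bp, "standard")
  }
  if (refine) {
    hi <- rep(min(max(tfn), 1), 2)
    ref <- lapply(bps, function(b) {
      # refine the kink positions (smooth in the objective) with the onset
      # held fixed, then rescan the onset partition, then re-refine
      for (pass in 1:2) {
        r <- tryCatch(stats::nlminb(b[2:3], function(kk) obj(c(b[1], kk)),
                                    lower = rep(b[1] + 1e-6, 2), upper = hi,
                                    control = list(rel.tol = 1e-14,
                                                   x.tol = 1e-12)),
                      error = function(e) NULL)
        if (!is.null(r)) b[2:3] <- r$par
        b[1] <- .scan_t0(tfn, n, b[2], b[3])
      }
      b
    })
    bps <- c(bps, ref)
    for (b in ref) {
      pol <- .polish_standard(tfn, n, b)
      if (!is.null(pol)) {
        pol[1] <- .scan_t0(tfn, n, pol[2], pol[3])
        bps <- c(bps, list(pol))
      }
    }
  }
  rss <- vapply(bps, function(b) obj(b), numeric(1))
  best <- bps[[which.min(rss)]]
  .finalize(tfn, n, best, "standard")
}

.md_fit_extended <- function(tfn, n, grid_step, min_seg, refine) {
  std <- .md_fit_standard(tfn, n, grid_step, min_seg, refine = TRUE)
  T0 <- std$T_fn1  # the true plateau in ramped data often maps here; scan both
  anchors <- unique(c(std$T_fn0, std$T_fn1))
  best <- NULL
  grid <- seq(min(tfn), max(tfn), by = grid_step)
  for (T0a in anchors) {
    ons <- grid[grid < T0a - grid_step / 2]
    if (!length(ons)) ons <- min(tfn) - grid_step
    T1a <- grid[grid > T0a & grid < max(tfn) - 2 * grid_step]
    for (o in ons) for (T1 in T1a) {
      txs <- grid[grid > T1 + grid_step / 2 & grid < max(tfn)]
      for (tx in txs) {
        t2s <- grid[grid > tx & grid <= min(max(tfn), 1)]
        if (!length(t2s)) next
        t2 <- t2s[which.min(abs(t2s - (tx + max(tfn)) / 2))]
        bp <- c(o, T0a, T1, tx, t2)
        if (any(diff(bp) <= 0)) next
        r <- .rss_for_bp(tfn, n, bp, "extended")
        if (is.null(best) || r < best$rss) best <- list(bp = bp, rss = r)
      }
    }
  }
  if (is.null(best)) stop("no admissible extended breakpoint set found")
  bp <- best$bp
  obj <- function(b) {
    if (any(diff(b) <= 1e-6) || b[5] > 1) return(1e6)
    .rss_for_bp(tfn, n, b, "extended")
  }
  # deterministic coordinate scans, then joint refinement
  for (cycle in 1:3) {
    for (k in 1:5) {
      cand <- bp[k] + seq(-0.02, 0.02, by = 0.002)
      for (v in cand) {
        b2 <- bp; b2[k] <- v
        if (any(diff(b2) <= 1e-6) || b2[5] > 1) next
        if (obj(b2) < obj(bp)) bp <- b2
      }
    }
  }
  if (refine) {
    r <- tryCatch(stats::nlminb(bp, obj,
                                lower = rep(min(tfn) - grid_step, 5),
                                upper = c(rep(min(max(tfn), 1), 4), 1),
                                control = list(rel.tol = 1e-14,
                                               x.tol = 1e-12)),
                  error = function(e) NULL)
    if (!is.null(r) && r$objective <= obj(bp)) bp <- r$par
  }
  .finalize(tfn, n, bp, "extended")
}

#' Differential melting diagram
#'
#' Analytic derivative `dn/dT_fn` of a fitted melting curve, evaluated on a
#' grid: zero on the plateau, the linear slope on the linear segment(s), and
#' `B + 2C (T_fn - T_fn2)` beyond the quadratic onset.  For the extended
#' variant the jump at `T_fn1` is rendered, when `spike = TRUE`, as a
#' single-bin rectangular spike of height `delta / step` on
#' `[T_fn1, T_fn1 + step)`, so that its trapezoid integral equals `delta`.
#'
#' With `refine_breaks = TRUE` (default) the requested grid is augmented with
#' points at and just below every slope discontinuity, which makes the
#' trapezoid rule exact (to rounding) on every segment: the integral of the
#' differential over `[T_fn0, 1]` then equals `n(1) - A` (including the jump
#' when the spike is rendered, `n(1) - A - delta` when it is not).
#'
#' @param p an [md_params()] object.
#' @param grid evaluation grid (strictly increasing); default
#'   `seq(T_fn0, 1, by = 0.001)`.
#' @param spike render the extended-variant jump as a finite spike.
#' @param refine_breaks augment the grid around discontinuities.
#' @return An [md_series()] with `kind = "differential"`.
#' @export
md_differential <- function(p, grid = NULL, spike = TRUE,
                            refine_breaks = TRUE) {
  stopifnot(inherits(p, "md_params"))
  if (is.null(grid)) grid <- seq(p$T_fn0, 1, by = 0.001)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  step <- stats::median(diff(grid))
  eps <- 1e-9
  disc <- if (p$variant == "standard") {
    c(p$T_fn1, p$T_fn2)
  } else {
    c(p$T_fn_onset, p$T_fn0, p$T_fn1, p$T_fn1 + step, p$T_fnx, p$T_fn2)
  }
  if (refine_breaks) {
    disc <- disc[disc > min(grid) & disc < max(grid)]
    grid <- sort(unique(c(grid, disc, disc - eps)))
  }
  d <- .md_deriv(p, grid)
  if (p$variant == "extended" && spike && p$delta > 0) {
    in_bin <- grid >= p$T_fn1 & grid < p$T_fn1 + step
    d[in_bin] <- d[in_bin] + p$delta / step
  }
  out <- md_series(grid, d, kind = "differential")
  attr(out, "spike_width") <- step
  attr(out, "params") <- p
  out
}

.md_deriv <- function(p, tfn) {
  if (p$variant == "standard") {
    d <- numeric(length(tfn))
    d[tfn >= p$T_fn1] <- p$B
    j <- tfn >= p$T_fn2
    d[j] <- p$B + 2 * p$C * (tfn[j] - p$T_fn2)
  } else {
    d <- numeric(length(tfn))
    ramp <- tfn >= p$T_fn_onset & tfn < p$T_fn0
    d[ramp] <- p$A / (p$T_fn0 - p$T_fn_onset)
    d[tfn >= p$T_fn1] <- p$B1
    d[tfn >= p$T_fnx] <- p$B2
    j <- tfn >= p$T_fn2
    d[j] <- p$B2 + 2 * p$C * (tfn[j] - p$T_fn2)
  }
  d
}

#' Classify a melting diagram as IDP-like or globular-like
#'
#' Globular proteins show a wide plateau of constant mobile hydration, while
#' intrinsically disordered proteins show a steadily growing mobile-water
#' fraction.  A fitted curve is called globular-like when the plateau spans
#' at least `plateau_frac` of the temperature range above the onset **and**
#' the post-plateau rise contributes less than `rise_frac` of the mobile
#' fraction at `T_fn = 1`; otherwise it is IDP-like.
#'
#' @param x an [md_params()] object, or an [md_series()] (fitted with the
#'   standard variant first).
#' @param plateau_frac minimum relative plateau span for a globular call.
#' @param rise_frac maximum relative post-plateau rise for a globular call.
#' @param ... passed to [md_fit()] when `x` is a series.
#' @return `"globular-like"` or `"IDP-like"`, with attributes
#'   `plateau_span` and `rise_fraction`.
#' @export
md_classify <- function(x, plateau_frac = 0.5, rise_frac = 0.5, ...) {
  p <- if (inherits(x, "md_series")) md_fit(x, ...) else x
  stopifnot(inherits(p, "md_params"))
  span <- (p$T_fn1 - p$T_fn0) / (1 - p$T_fn0)
  n1 <- md_evaluate(p, 1)
  rise <- if (n1 > 0) (n1 - p$A) / n1 else 0
  lab <- if (span >= plateau_frac && rise < rise_frac) "globular-like"
         else "IDP-like"
  structure(lab, plateau_span = span, rise_fraction = rise)
}
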