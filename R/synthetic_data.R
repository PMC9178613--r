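# Seeded generators for every input the pipeline consumes.  All of them
# restore the caller's RNG state, so a fixed `seed` argument gives
# reproducible output without side effects.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # initialize RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a melting diagram from known parameters
#'
#' Evaluates the piecewise melting-curve model on a grid and adds
#' homoscedastic Gaussian noise, clipped at zero (a mobile fraction cannot be
#' negative).  The default noise level `sigma = 5e-4` is about 3% of a
#' typical plateau amplitude.  The generating truth and seed are recorded as
#' attributes, so parameter-recovery tests can compare against them.
#'
#' @param params an [md_params()] truth object.
#' @param grid strictly increasing `T_fn` grid.
#' @param sigma standard deviation of the additive noise on `n` (>= 0).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param sample optional [sample_info()] attached to the series.
#' @return An [md_series()] with `kind = "measured"` and attributes `truth`
#'   and `seed`.
#' @examples
#' truth <- md_params(A = 0.0156, B = 0.24, C = 50,
#'                    T_fn0 = 0.824, T_fn1 = 0.879, T_fn2 = 0.959)
#' md <- gen_md(truth, seed = 1)
#' @export
gen_md <- function(params, grid = seq(0.80, 1.00, length.out = 40),
                   sigma = 5e-4, seed = NULL, sample = NULL) {
  stopifnot(inherits(params, "md_params"))
  if (sigma < 0) stop("sigma must be >= 0")
  n <- md_evaluate(params, grid)
  if (sigma > 0) {
    n <- .with_seed(seed, n + stats::rnorm(length(grid), sd = sigma))
    n <- pmax(n, 0)
  }
  out <- md_series(grid, n, sample = sample, kind = "measured")
  attr(out, "truth") <- params
  attr(out, "seed") <- seed
  out
}

#' Simulate an ensemble of secondary-structure predictor tracks
#'
#' Corrupts a true label string independently per residue: with probability
#' `err` the label is replaced by a symbol drawn uniformly from the *other*
#' symbols of the alphabet.  Emulates an ensemble of imperfect predictors
#' with independent errors (real predictors are correlated; see the package
#' vignette for what that implies).
#'
#' @param truth an [ss_track()] (or label string) with the true labels.
#' @param m number of predictor tracks to generate.
#' @param err per-residue error rate in \[0, 1).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @return List of `m` [ss_track()] objects named `sim1 ... simm`.
#' @export
gen_ss_ensemble <- function(truth, m = 5L, err = 0.1, seed = NULL) {
  if (!inherits(truth, "ss_track")) truth <- ss_track(truth)
  if (err < 0 || err >= 1) stop("err must lie in [0, 1)")
  chars <- strsplit(truth$labels, "")[[1]]
  alpha <- if (truth$alphabet == "three_state") .THREE_STATE else .EIGHT_STATE
  L <- length(chars)
  .with_seed(seed, {
    lapply(seq_len(m), function(j) {
      out <- chars
      flip <- stats::runif(L) < err
      if (any(flip)) {
        out[flip] <- vapply(out[flip], function(sym)
          sample(setdiff(alpha, sym), 1L), character(1))
      }
      ss_track(paste(out, collapse = ""), predictor = paste0("sim", j),
               alphabet = truth$alphabet)
    })
  })
}

#' Simulate a per-residue score track
#'
#' Builds a piecewise-constant score profile from segment means, adds
#' Gaussian noise and clips to \[0, 1\].  The segments must tile
#' `[1, L]` without gaps or overlaps.
#'
#' @param segments data frame (or list of vectors) with columns/elements
#'   `start`, `end`, `mean`: 1-based inclusive segment bounds and segment
#'   mean scores in \[0, 1\].
#' @param sigma standard deviation of the additive noise.
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param source passed to [score_track()].
#' @return A [score_track()] of length `max(end)` with attributes `segments`
#'   and `seed`.
#' @examples
#' seg <- data.frame(start = c(1, 83), end = c(82, 140),
#'                   mean = c(0.3, 0.9))
#' tr <- gen_score_track(seg, sigma = 0.02, seed = 7)
#' call_regions(tr)  # one region near 83..140
#' @export
gen_score_track <- function(segments, sigma = 0.02, seed = NULL,
                            source = "disorder") {
  if (!is.data.frame(segments)) segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "mean") %in% names(segments)))
  seg <- segments[order(segments$start), ]
  if (seg$start[1] != 1L || any(seg$start > seg$end))
    stop("segments must start at 1 with start <= end")
  if (nrow(seg) > 1L && any(seg$start[-1] != seg$end[-nrow(seg)] + 1L))
    stop("segments must tile [1, L] without gaps or overlaps")
  if (any(seg$mean < 0 | seg$mean > 1)) stop("segment means must lie in [0, 1]")
  if (sigma < 0) stop("sigma must be >= 0")
  L <- max(seg$end)
  mu <- numeric(L)
  for (i in seq_len(nrow(seg))) mu[seg$start[i]:seg$end[i]] <- seg$mean[i]
  scores <- if (sigma > 0)
    .with_seed(seed, pmin(pmax(mu + stats::rnorm(L, sd = sigma), 0), 1))
  else mu
  out <- score_track(scores, source = source)
  attr(out, "segments") <- seg
  attr(out, "seed") <- seed
  out
}
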