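.THREE_STATE <- c("H", "E", "C")
.EIGHT_STATE <- c("G", "H", "I", "E", "B", "T", "S", "L")
# DSSP 8-to-3 grouping: helical G/H/I -> H, strand E/bridge B -> E,
# turn/bend/other T/S/L -> C.
.MAP_8_TO_3 <- c(G = "H", H = "H", I = "H", E = "E", B = "E",
                 T = "C", S = "C", L = "C")

#' Per-residue secondary-structure track
#'
#' A predictor's per-residue secondary-structure string, in either the
#' three-state alphabet (H helix, E strand, C coil) or the DSSP eight-state
#' alphabet (G, H, I, E, B, T, S, L).
#'
#' @param labels per-residue label string (or character vector of single
#'   letters).
#' @param predictor name of the predictor that produced the track.
#' @param alphabet `"three_state"` or `"eight_state"`; guessed from the
#'   symbols when omitted (a track using only H/E/C letters is three-state).
#' @return An object of class `"ss_track"` with fields `predictor`,
#'   `alphabet`, `labels`.
#' @export
ss_track <- function(labels, predictor = "track", alphabet = NULL) {
  if (length(labels) > 1L) labels <- paste(labels, collapse = "")
  labels <- toupper(labels)
  chars <- strsplit(labels, "")[[1]]
  if (is.null(alphabet)) {
    alphabet <- if (all(chars %in% .THREE_STATE)) "three_state"
                else "eight_state"
  }
  alphabet <- match.arg(alphabet, c("three_state", "eight_state"))
  valid <- if (alphabet == "three_state") .THREE_STATE else .EIGHT_STATE
  bad <- which(!chars %in% valid)
  if (length(bad))
    stop(sprintf("unknown %s symbol '%s' at position %d",
                 gsub("_", "-", alphabet), chars[bad[1]], bad[1]))
  structure(list(predictor = predictor, alphabet = alphabet, labels = labels),
            class = "ss_track")
}

#' @export
print.ss_track <- function(x, ...) {
  cat(sprintf("SS track '%s' (%s, %d residues)\n", x$predictor,
              gsub("_", "-", x$alphabet), nchar(x$labels)))
  invisible(x)
}

#' Map an eight-state track to three states
#'
#' DSSP-style grouping: G, H, I -> H (helical); E, B -> E (strand);
#' T, S, L -> C (coil).
#'
#' @param t an [ss_track()] with `alphabet = "eight_state"` (a three-state
#'   track is returned unchanged).
#' @return A three-state [ss_track()] of the same length.
#' @examples
#' map_8_to_3(ss_track("GHIEBTSL"))$labels  # "HHHEECCC"
#' @export
map_8_to_3 <- function(t) {
  stopifnot(inherits(t, "ss_track"))
  if (t$alphabet == "three_state") return(t)
  chars <- strsplit(t$labels, "")[[1]]
  ss_track(paste(.MAP_8_TO_3[chars], collapse = ""),
           predictor = t$predictor, alphabet = "three_state")
}

#' Reassign short secondary-structure runs to coil
#'
#' Secondary-structure elements shorter than `k` consecutive residues are
#' not counted: H and E runs of length `< k` are reassigned to C.  Coil runs
#' are never reassigned.  The filter is idempotent and never increases the
#' H + E content.
#'
#' @param labels a three-state label string (or an [ss_track()]).
#' @param k minimum run length for a structured element (default 4).
#' @return Filtered label string (or track, matching the input type).
#' @examples
#' min_run_filter("CHHHC")   # "CCCCC"
#' min_run_filter("CHHHHC")  # unchanged
#' @export
min_run_filter <- function(labels, k = 4L) {
  if (k < 1L) stop("k must be >= 1")
  trk <- inherits(labels, "ss_track")
  s <- if (trk) labels$labels else labels
  chars <- strsplit(toupper(s), "")[[1]]
  if (!length(chars)) return(labels)
  r <- rle(chars)
  short <- r$values %in% c("H", "E") & r$lengths < k
  r$values[short] <- "C"
  out <- paste(inverse.rle(r), collapse = "")
  if (trk) ss_track(out, predictor = labels$predictor,
                    alphabet = "three_state")
  else out
}

#' Consensus of secondary-structure predictor tracks
#'
#' Aggregates several per-residue secondary-structure tracks into a
#' consensus by per-residue plurality vote (ties go to coil, the "remaining"
#' class), followed by the minimum-run filter ([min_run_filter()]).
#' Eight-state tracks are mapped to three states first.  Composition is
#' computed after filtering.
#'
#' @param tracks list of [ss_track()] objects of equal length (at least
#'   one).
#' @param k minimum run length passed to [min_run_filter()]; use `k = 1` to
#'   disable filtering.
#' @return An object of class `"ss_consensus"`: list with `labels` (the
#'   consensus string), `runs` (data frame of `state`, `start`, `end`,
#'   1-based inclusive, tiling the sequence) and `composition` (named
#'   fractions over H, E, C summing to 1).
#' @export
ss_consensus <- function(tracks, k = 4L) {
  if (inherits(tracks, "ss_track")) tracks <- list(tracks)
  if (!length(tracks)) stop("at least one track is required")
  tracks <- lapply(tracks, function(t) {
    if (!inherits(t, "ss_track")) t <- ss_track(t)
    map_8_to_3(t)
  })
  L <- nchar(tracks[[1]]$labels)
  lens <- vapply(tracks, function(t) nchar(t$labels), integer(1))
  if (any(lens != L))
    stop("track length mismatch: ", paste(unique(lens), collapse = ", "))
  mat <- do.call(rbind, lapply(tracks, function(t) strsplit(t$labels, "")[[1]]))
  vote <- vapply(seq_len(L), function(i) {
    tab <- table(factor(mat[, i], levels = .THREE_STATE))
    top <- which(tab == max(tab))
    if (length(top) > 1L) "C" else .THREE_STATE[top]
  }, character(1))
  labels <- min_run_filter(paste(vote, collapse = ""), k = k)
  chars <- strsplit(labels, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  runs <- data.frame(state = r$values,
                     start = ends - r$lengths + 1L,
                     end = ends)
  comp <- as.numeric(table(factor(chars, levels = .THREE_STATE))) / L
  names(comp) <- .THREE_STATE
  structure(list(labels = labels, runs = runs, composition = comp,
                 n_tracks = length(tracks)),
            class = "ss_consensus")
}

#' @export
print.ss_consensus <- function(x, ...) {
  cat(sprintf("Secondary-structure consensus of %d track(s), %d residues\n",
              x$n_tracks, nchar(x$labels)))
  cat(sprintf("  composition: H %.1f%%  E %.1f%%  C %.1f%%\n",
              100 * x$composition["H"], 100 * x$composition["E"],
              100 * x$composition["C"]))
  cat(sprintf("  %d runs\n", nrow(x$runs)))
  invisible(x)
}

#' Per-residue score track (disorder or disordered-binding propensity)
#'
#' IUPred2/ANCHOR2-style per-residue scores in \[0, 1\]; values strictly
#' above 0.5 indicate a disordered region or a disordered binding site.
#'
#' @param scores numeric vector of per-residue scores in \[0, 1\].
#' @param source `"disorder"` or `"binding"`.
#' @return An object of class `"score_track"`.
#' @export
score_track <- function(scores, source = c("disorder", "binding")) {
  source <- match.arg(source)
  if (!is.numeric(scores) || !length(scores))
    stop("`scores` must be a non-empty numeric vector")
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1))
    stop("scores must lie in [0, 1]")
  structure(list(source = source, scores = as.numeric(scores)),
            class = "score_track")
}

#' @export
print.score_track <- function(x, ...) {
  cat(sprintf("%s score track, %d residues, mean %.3f\n",
              x$source, length(x$scores), mean(x$scores)))
  invisible(x)
}

#' Call regions of elevated score
#'
#' Finds maximal runs of residues with scores strictly above the threshold
#' (a score exactly at the threshold is not called).
#'
#' @param s a [score_track()].
#' @param thr threshold (default 0.5).
#' @return Data frame with columns `start`, `end` (1-based inclusive) and
#'   `mean_score`; zero rows when nothing exceeds the threshold.
#' @export
call_regions <- function(s, thr = 0.5) {
  stopifnot(inherits(s, "score_track"))
  above <- s$scores > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = starts[keep], end = ends[keep])
  out$mean_score <- vapply(seq_len(nrow(out)), function(i)
    mean(s$scores[out$start[i]:out$end[i]]), numeric(1))
  out
}

#' Mean score over a residue window
#'
#' @param s a [score_track()].
#' @param start,end 1-based inclusive window bounds with
#'   `1 <= start <= end <= length`.
#' @return Arithmetic mean of the scores in the window.
#' @export
mean_score <- function(s, start, end) {
  stopifnot(inherits(s, "score_track"))
  L <- length(s$scores)
  if (start < 1L || end > L || start > end)
    stop(sprintf("bad window [%d, %d] for a track of length %d",
                 start, end, L))
  mean(s$scores[start:end])
}

#' Read secondary-structure tracks from plain text
#'
#' One track per line, either `name<TAB>labels` or a bare label string (then
#' tracks are named `track1`, `track2`, ...).  Blank lines and lines starting
#' with `#` are skipped.
#'
#' @param path input file.
#' @return List of [ss_track()] objects.
#' @export
read_ss_tracks <- function(path) {
  if (!file.exists(path)) stop("track file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) stop("no tracks in ", path)
  lapply(seq_along(lines), function(i) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2L) ss_track(parts[2], predictor = parts[1])
    else ss_track(parts[1], predictor = paste0("track", i))
  })
}

#' Read a per-residue score track from plain text
#'
#' Either one score per line, or two whitespace-separated columns
#' (residue index, score); an optional non-numeric header line is skipped.
#'
#' @param path input file.
#' @param source passed to [score_track()].
#' @return A [score_track()].
#' @export
read_score_track <- function(path, source = "disorder") {
  if (!file.exists(path)) stop("score file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no scores in ", path)
  toks <- strsplit(lines, "[,\t ]+")
  # drop an optional non-numeric header line
  if (anyNA(suppressWarnings(as.numeric(toks[[1]])))) toks <- toks[-1]
  if (!length(toks)) stop("no scores in ", path)
  wid <- lengths(toks)
  if (any(wid != wid[1])) stop("ragged score file: ", path)
  num <- do.call(rbind, lapply(toks, as.numeric))
  if (anyNA(num)) stop("non-numeric score values in ", path)
  scores <- if (ncol(num) >= 2L) num[order(num[, 1]), 2] else num[, 1]
  score_track(scores, source = source)
}
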