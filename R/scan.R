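# Both-strand PWM scanning and empirical score-threshold calibration.
# Sequences are encoded once (A=1, C=2, G=3, T=4, anything else 0) and
# scored by accumulating log-odds rows over all windows of the
# concatenated corpus at once; windows straddling sequence boundaries are
# masked out. Bases coded 0 (N etc.) score 0 bits, i.e. background.

encode_seqs <- function(seqs) {
  if (inherits(seqs, "encoded_seqs")) return(seqs)
  if (methods::is(seqs, "DNAStringSet") || methods::is(seqs, "DNAString"))
    seqs <- as.character(seqs)
  lut <- integer(256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("a")] <- 1L
  lut[utf8ToInt("C")] <- 2L; lut[utf8ToInt("c")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("g")] <- 3L
  lut[utf8ToInt("T")] <- 4L; lut[utf8ToInt("t")] <- 4L
  structure(list(codes = unlist(lapply(seqs, function(s)
                   lut[utf8ToInt(s)]), use.names = FALSE),
                 lens = vapply(seqs, nchar, integer(1), USE.NAMES = FALSE),
                 ids = names(seqs)),
            class = "encoded_seqs")
}

# Scores of every boundary-respecting window on both strands (compiled
# kernel). Returns seq index, 0-based local start and forward/reverse
# scores.
window_scores <- function(enc, lo) {
  scan_scores_cpp(enc$codes, enc$lens, lo)
}

#' Calibrate a PWM score threshold to a target site frequency
#'
#' Finds the least stringent (smallest) score threshold whose empirical
#' both-strand hit rate on the background does not exceed `target_rate`.
#' The rate denominator is the number of scannable positions (windows on
#' the forward strand); hits on either strand count.
#'
#' @param pwm a `pwm` with `log_odds` filled (see [log_odds_matrix()]).
#' @param background_seqs background sequences ([Biostrings::DNAStringSet]
#'   or character vector); total length must be at least
#'   `100 / target_rate` so the rate is resolvable.
#' @param target_rate sites per bp, e.g. `1/2000` for enrichment scanning
#'   or `1/50000` for the motif-overlap analysis.
#' @return A list of class `threshold_calibration`: `matrix_id`,
#'   `target_rate`, `threshold` (bits), `achieved_rate`, `n_positions`.
#' @export
calibrate_threshold <- function(pwm, background_seqs, target_rate) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(pwm$log_odds))
    stop("call log_odds_matrix() before calibrating", call. = FALSE)
  if (target_rate <= 0) stop("target_rate must be positive", call. = FALSE)
  enc <- encode_seqs(background_seqs)
  total_bp <- sum(enc$lens)
  required <- ceiling(100 / target_rate)
  if (total_bp < required)
    stop(sprintf("background too short: %d bp given, >= %d bp required to resolve a rate of %g",
                 total_bp, required, target_rate), call. = FALSE)
  ws <- window_scores(enc, pwm$log_odds)
  npos <- length(ws$start)
  scores <- c(ws$fwd, ws$rev)
  m <- floor(target_rate * npos)
  N <- length(scores)
  if (m >= N) {
    threshold <- min(scores)
  } else if (m == 0L) {
    threshold <- max(scores) + 1
  } else {
    # m-th largest = (N - m + 1)-th smallest; partial selection, O(N)
    threshold <- sort(scores, partial = N - m + 1L)[N - m + 1L]
    if (sum(scores >= threshold) > m) {      # ties push the rate over
      higher <- scores[scores > threshold]
      threshold <- if (length(higher)) min(higher) else max(scores) + 1
    }
  }
  structure(list(matrix_id = pwm$matrix_id, target_rate = target_rate,
                 threshold = threshold,
                 achieved_rate = sum(scores >= threshold) / npos,
                 n_positions = npos),
            class = "threshold_calibration")
}

#' Scan sequences with a PWM on both strands
#'
#' Every window of the matrix length whose log-odds score reaches
#' `threshold` is reported, on either strand, in forward coordinates of
#' the scanned sequence (0-based half-open). Overlapping above-threshold
#' windows of the same matrix are all reported.
#'
#' @param seqs sequences ([Biostrings::DNAStringSet] or named character
#'   vector).
#' @param pwm a `pwm` with `log_odds` filled.
#' @param threshold score threshold in bits (from
#'   [calibrate_threshold()]).
#' @return data.frame with columns `promoter_id, start, end, matrix_id,
#'   score, strand`.
#' @export
scan_sequences <- function(seqs, pwm, threshold) {
  stopifnot(inherits(pwm, "pwm"))
  if (is.null(pwm$log_odds))
    stop("call log_odds_matrix() before scanning", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  enc <- encode_seqs(seqs)
  ids <- enc$ids
  if (is.null(ids)) ids <- as.character(seq_along(enc$codes))
  ws <- window_scores(enc, pwm$log_odds)
  hf <- ws$fwd >= threshold
  hr <- ws$rev >= threshold
  starts <- c(ws$start[hf], ws$start[hr])
  out <- data.frame(
    promoter_id = ids[c(ws$seq_idx[hf], ws$seq_idx[hr])],
    start = starts,
    end = starts + pwm$length,
    matrix_id = rep_len(pwm$matrix_id, length(starts)),
    score = c(ws$fwd[hf], ws$rev[hr]),
    strand = rep(c("+", "-"), c(sum(hf), sum(hr))),
    stringsAsFactors = FALSE)
  out <- out[order(out$promoter_id, out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Scan a promoter corpus with a PWM library at calibrated thresholds
#'
#' Convenience wrapper: per matrix, looks up (or computes) its calibrated
#' threshold and scans.
#'
#' @param seqs sequences to scan.
#' @param pwms list of `pwm` objects with log-odds filled.
#' @param calibrations list of `threshold_calibration`s covering every
#'   matrix.
#' @return Combined hit data.frame as in [scan_sequences()].
#' @export
scan_library <- function(seqs, pwms, calibrations) {
  thr <- stats::setNames(
    vapply(calibrations, `[[`, numeric(1), "threshold"),
    vapply(calibrations, `[[`, character(1), "matrix_id"))
  enc <- encode_seqs(seqs)   # encode the corpus once for all matrices
  hits <- lapply(pwms, function(p) {
    if (is.na(thr[p$matrix_id]))
      stop(sprintf("no calibration for matrix '%s'", p$matrix_id),
           call. = FALSE)
    scan_sequences(enc, p, thr[[p$matrix_id]])
  })
  do.call(rbind, hits)
}
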