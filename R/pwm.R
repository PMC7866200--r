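# Position weight matrices: construction, flat-file dialects (TRANSFAC-
# style and JASPAR-style), and log-odds scoring matrices. Counts are kept
# exactly as parsed; probabilities and log-odds are derived views.

#' Construct a position weight matrix object
#'
#' @param matrix_id matrix identifier.
#' @param tf_names character vector of TF names owning the matrix (a TF
#'   may own several matrices).
#' @param counts L x 4 non-negative matrix, columns `A, C, G, T`.
#' @return An object of class `pwm` with `matrix_id`, `tf_names`,
#'   `counts`, `probabilities` (rows sum to 1), `length` and (after
#'   [log_odds_matrix()]) `log_odds`.
#' @export
new_pwm <- function(matrix_id, tf_names, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) == 0L) stop("zero-length matrix", call. = FALSE)
  if (ncol(counts) != 4L) stop("counts must have 4 columns", call. = FALSE)
  if (any(counts < 0)) stop("negative count in PWM", call. = FALSE)
  tot <- rowSums(counts)
  if (any(tot <= 0)) stop("PWM column with zero total count", call. = FALSE)
  colnames(counts) <- c("A", "C", "G", "T")
  structure(list(matrix_id = matrix_id,
                 tf_names = as.character(tf_names), counts = counts,
                 probabilities = counts / tot, log_odds = NULL,
                 length = nrow(counts)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm '%s' (%s): %d bp%s\n", x$matrix_id,
              paste(x$tf_names, collapse = ";"), x$length,
              if (is.null(x$log_odds)) "" else ", log-odds ready"))
  invisible(x)
}

#' Fill the log-odds scoring matrix of a PWM
#'
#' Per position `i` and base `b`:
#' `log2(((counts[i,b] + pseudocount * background[b]) /
#' (total[i] + pseudocount)) / background[b])`, in bits. The pseudocount
#' is distributed according to the background (Laplace-with-background),
#' keeping scores finite for zero counts.
#'
#' @param pwm a `pwm`.
#' @param background length-4 base probabilities (A, C, G, T), summing
#'   to 1, all positive.
#' @param pseudocount positive real (default 1).
#' @return The `pwm` with its `log_odds` slot filled.
#' @export
log_odds_matrix <- function(pwm, background = rep(0.25, 4),
                            pseudocount = 1) {
  stopifnot(inherits(pwm, "pwm"))
  if (length(background) != 4L || abs(sum(background) - 1) > 1e-9)
    stop("background must be 4 probabilities summing to 1", call. = FALSE)
  if (any(background <= 0))
    stop("background probabilities must all be positive", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  tot <- rowSums(pwm$counts)
  p <- sweep(pwm$counts, 2, background * pseudocount, `+`) /
    (tot + pseudocount)
  pwm$log_odds <- log2(sweep(p, 2, background, `/`))
  pwm$background <- background
  pwm$pseudocount <- pseudocount
  pwm
}

# ---- flat-file dialects ----------------------------------------------

parse_transfac <- function(lines) {
  pwms <- list()
  id <- NULL; tf <- character(); rows <- NULL; col_order <- c("A","C","G","T")
  flush <- function() {
    if (is.null(id) && is.null(rows)) return()
    if (is.null(id)) stop("TRANSFAC block without AC identifier",
                          call. = FALSE)
    if (is.null(rows) || nrow(rows) == 0L)
      stop(sprintf("zero-length matrix in block '%s'", id), call. = FALSE)
    m <- rows[, match(c("A", "C", "G", "T"), col_order), drop = FALSE]
    pwms[[length(pwms) + 1L]] <<- new_pwm(id, if (length(tf)) tf else id, m)
    id <<- NULL; tf <<- character(); rows <<- NULL
    col_order <<- c("A", "C", "G", "T")
  }
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || line == "XX") next
    if (line == "//") { flush(); next }
    tag <- substr(line, 1, 2)
    rest <- trimws(substr(line, 3, nchar(line)))
    if (tag == "AC") { id <- rest }
    else if (tag == "ID") { if (is.null(id)) id <- rest }
    else if (tag == "NA") { tf <- trimws(strsplit(rest, ";")[[1]]) }
    else if (tag == "P0" || tag == "PO") {
      col_order <- strsplit(rest, "\\s+")[[1]]
      if (!setequal(col_order, c("A", "C", "G", "T")))
        stop(sprintf("line %d: P0 header must name bases A C G T", ln),
             call. = FALSE)
    } else if (grepl("^[0-9]+$", tag) || grepl("^[0-9]", line)) {
      fields <- strsplit(line, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(fields[2:5]))
      if (length(fields) < 5L || anyNA(vals))
        stop(sprintf("line %d: malformed TRANSFAC matrix row: '%s'",
                     ln, line), call. = FALSE)
      if (any(vals < 0))
        stop(sprintf("line %d: negative count", ln), call. = FALSE)
      r <- matrix(vals, 1, 4, dimnames = list(NULL, col_order))
      rows <- rbind(rows, r)
    } else {
      # unknown annotation tags are tolerated
    }
  }
  flush()
  pwms
}

parse_jaspar <- function(lines) {
  pwms <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!startsWith(line, ">"))
      stop(sprintf("line %d: expected '>' record header", i), call. = FALSE)
    hdr <- strsplit(sub("^>\\s*", "", line), "\\s+")[[1]]
    id <- hdr[1]
    tf <- if (length(hdr) > 1) hdr[-1] else id
    vals <- list()
    for (b in c("A", "C", "G", "T")) {
      i <- i + 1L
      if (i > length(lines))
        stop(sprintf("truncated JASPAR record '%s'", id), call. = FALSE)
      row <- trimws(lines[i])
      if (!startsWith(row, b))
        stop(sprintf("line %d: expected row for base %s", i, b),
             call. = FALSE)
      nums <- suppressWarnings(as.numeric(
        strsplit(trimws(gsub("[][]", " ", substr(row, 2, nchar(row)))),
                 "\\s+")[[1]]))
      if (!length(nums) || anyNA(nums))
        stop(sprintf("line %d: malformed JASPAR count row", i),
             call. = FALSE)
      if (any(nums < 0))
        stop(sprintf("line %d: negative count", i), call. = FALSE)
      vals[[b]] <- nums
    }
    if (length(unique(lengths(vals))) != 1L)
      stop(sprintf("record '%s': ragged count rows", id), call. = FALSE)
    counts <- cbind(A = vals$A, C = vals$C, G = vals$G, T = vals$T)
    pwms[[length(pwms) + 1L]] <- new_pwm(id, tf, counts)
    i <- i + 1L
  }
  pwms
}

#' Parse a PWM library from a flat file
#'
#' Two dialects are supported: `transfac` (AC/ID/NA annotation tags, a
#' `P0 A C G T` header and numbered count rows, blocks terminated by
#' `//`) and `jaspar` (`>` headers followed by four bracketed count rows
#' `A [ ... ]` ... `T [ ... ]`). Counts are preserved exactly.
#'
#' @param path file path.
#' @param dialect `"transfac"` or `"jaspar"`.
#' @return A list of `pwm` objects.
#' @export
parse_pwms <- function(path, dialect = c("transfac", "jaspar")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  lines <- readLines(path)
  pwms <- switch(dialect, transfac = parse_transfac(lines),
                 jaspar = parse_jaspar(lines))
  if (!length(pwms)) stop(sprintf("%s: no matrices found", path),
                          call. = FALSE)
  pwms
}

#' Serialize a PWM library to a flat file
#'
#' @param pwms list of `pwm` objects.
#' @param path output path.
#' @param dialect `"transfac"` or `"jaspar"`.
#' @return Invisibly, `path`.
#' @export
write_pwms <- function(pwms, path, dialect = c("transfac", "jaspar")) {
  dialect <- match.arg(dialect)
  fmt_num <- function(x) {
    ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
           sprintf("%.6g", x))
  }
  out <- character(0)
  for (p in pwms) {
    if (dialect == "transfac") {
      out <- c(out,
               paste("AC", p$matrix_id), "XX",
               paste("ID", p$matrix_id), "XX",
               paste("NA", paste(p$tf_names, collapse = "; ")), "XX",
               paste("P0", "A", "C", "G", "T", sep = "\t"),
               vapply(seq_len(p$length), function(i)
                 paste(c(sprintf("%02d", i), fmt_num(p$counts[i, ])),
                       collapse = "\t"), character(1)),
               "XX", "//")
    } else {
      out <- c(out,
               sprintf(">%s %s", p$matrix_id,
                       paste(p$tf_names, collapse = ";")),
               vapply(c("A", "C", "G", "T"), function(b)
                 sprintf("%s [ %s ]", b,
                         paste(fmt_num(p$counts[, b]), collapse = " ")),
                 character(1)))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Map matrix ids to TF names across a library
#'
#' @param pwms list of `pwm` objects.
#' @return Named character vector, matrix id -> first TF name.
#' @export
matrix_tf_map <- function(pwms) {
  stats::setNames(vapply(pwms, function(p) p$tf_names[1], character(1)),
                  vapply(pwms, function(p) p$matrix_id, character(1)))
}
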