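# Internal helpers shared across modules.

#' Derive a child seed from a global seed and a salt label
#'
#' One global integer seed fans out to per-generator seeds so that each
#' synthetic-data module is independently reproducible. The derivation is a
#' fixed LCG step on `seed` offset by a deterministic hash of the salt
#' string, reduced modulo 2^31 - 1 (R integers are 32-bit).
#'
#' @param seed integer scalar.
#' @param salt character scalar naming the consumer (e.g. `"meta"`, `"pwm"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(salt))
  m <- 2147483647  # 2^31 - 1
  h <- 0
  for (v in utf8ToInt(salt)) h <- (h * 131 + v) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators never perturb user code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1], got %s",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x))
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  invisible(as.integer(x))
}

# One structured log line per stage; counts are the debugging surface.
stage_log <- function(stage, ...) {
  kv <- c(...)
  msg <- if (length(kv))
    paste(names(kv), unname(kv), sep = "=", collapse = " ") else ""
  message(sprintf("[%s] %s", stage, msg))
}

# Fixed-format TSV writer: byte-identical output for identical input.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
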