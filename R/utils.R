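# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the caller's RNG state afterwards. All stochastic operations in
#' the package route through this so that a scenario seed fully determines
#' its outputs.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a stage seed from a master seed. Kept below 2^31.
mix_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 50021) * 2654435 + as.numeric(offset) * 7919 + 12345
  as.integer(s %% 2147483647)
}

stopifnot_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("'%s' must be a single value in [0, 1]", name), call. = FALSE)
  invisible(x)
}

stopifnot_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) >= 1L && all(!is.na(x)) &&
    all(x == floor(x)) && all(x >= if (positive) 1 else 0)
  if (!ok) stop(sprintf("'%s' must be %s integer count(s)",
                        name, if (positive) "positive" else "non-negative"),
                call. = FALSE)
  invisible(x)
}

# Plain TSV I/O used for all tabular artifacts (stable column order, no quoting).
write_tsv <- function(df, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#",
             na.strings = "", check.names = FALSE, ...)
}

# Normalize a taxon name for exact matching: underscores to spaces, collapsed
# whitespace; a well-formed trinomial is truncated to its binomial (trees are
# requested without subspecies epithets). Epithets are at least two letters,
# so stray single-letter suffixes are not mistaken for subspecies.
normalize_name <- function(x) {
  x <- gsub("_", " ", x)
  x <- gsub("[[:space:]]+", " ", trimws(x))
  vapply(x, function(nm) {
    toks <- strsplit(nm, " ", fixed = TRUE)[[1]]
    if (length(toks) >= 3L &&
        grepl("^[A-Z][a-z-]+$", toks[1]) &&
        all(grepl("^[a-z][a-z-]+$", toks[-1])))
      paste(toks[1:2], collapse = " ")
    else nm
  }, character(1), USE.NAMES = FALSE)
}

is_binomial <- function(x) grepl("^[A-Z][a-z-]+ [a-z][a-z-]+$", x)
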