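# Exact non-negative integer arithmetic for MPR counting.
#
# MPR counts grow multiplicatively over polytomies and routinely exceed what a
# 32-bit integer holds (the interesting cases exceed 1e14). Counting paths
# therefore use this little-endian base-10^4 representation throughout; no
# floating point is involved. Doubles appear only when counts are converted to
# sampling weights.

BI_BASE <- 10000L

bi <- function(x) {
  # exact small constructor; x must be a non-negative integer-valued double
  # representable exactly (< 2^53)
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0, x == floor(x))
  if (x == 0) return(structure(list(d = 0L), class = "big_integer"))
  d <- integer(0)
  while (x > 0) {
    d <- c(d, as.integer(x %% BI_BASE))
    x <- floor(x / BI_BASE)
  }
  structure(list(d = d), class = "big_integer")
}

bi_zero <- function() bi(0)
bi_one <- function() bi(1)

bi_norm <- function(d) {
  # carry-propagate a numeric digit vector, return integer digits
  carry <- 0
  out <- numeric(length(d) + 16)
  n <- 0L
  for (i in seq_along(d)) {
    v <- d[i] + carry
    out[i] <- v %% BI_BASE
    carry <- floor(v / BI_BASE)
    n <- i
  }
  i <- n
  while (carry > 0) {
    i <- i + 1L
    if (i > length(out)) out <- c(out, numeric(16))
    out[i] <- carry %% BI_BASE
    carry <- floor(carry / BI_BASE)
  }
  d <- as.integer(out[seq_len(max(i, 1L))])
  while (length(d) > 1L && d[length(d)] == 0L) d <- d[-length(d)]
  d
}

bi_add <- function(a, b) {
  da <- a$d; db <- b$d
  n <- max(length(da), length(db))
  da <- c(da, integer(n - length(da)))
  db <- c(db, integer(n - length(db)))
  structure(list(d = bi_norm(as.numeric(da) + as.numeric(db))),
            class = "big_integer")
}

bi_mul <- function(a, b) {
  da <- as.numeric(a$d); db <- as.numeric(b$d)
  if ((length(da) == 1L && da == 0) || (length(db) == 1L && db == 0))
    return(bi_zero())
  conv <- numeric(length(da) + length(db))
  for (i in seq_along(da)) {
    if (da[i] == 0) next
    idx <- seq_along(db) + i - 1L
    conv[idx] <- conv[idx] + da[i] * db
    # keep partial sums well below 2^53: digits < 1e4, products < 1e8,
    # at most ~1e7 accumulations before an interim normalization is needed;
    # normalize defensively for long operands
    if (i %% 1024L == 0L) conv <- as.numeric(bi_norm_partial(conv))
  }
  structure(list(d = bi_norm(conv)), class = "big_integer")
}

bi_norm_partial <- function(d) {
  # partial carry pass that keeps values in range without finalizing length
  carry <- 0
  for (i in seq_along(d)) {
    v <- d[i] + carry
    d[i] <- v %% BI_BASE
    carry <- floor(v / BI_BASE)
  }
  if (carry > 0) d <- c(d, bi_norm(carry))
  d
}

bi_sum <- function(xs) Reduce(bi_add, xs, accumulate = FALSE)

bi_eq <- function(a, b) identical(bi_norm(a$d), bi_norm(b$d))

#' @export
format.big_integer <- function(x, ...) {
  d <- rev(x$d)
  paste0(d[1], paste(sprintf("%04d", d[-1]), collapse = ""))
}

#' @export
print.big_integer <- function(x, ...) {
  cat("<big integer> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.big_integer <- function(x, ...) format(x)

#' @export
as.double.big_integer <- function(x, ...) {
  # approximate conversion, used only for sampling weights / display
  sum(as.numeric(x$d) * BI_BASE^(seq_along(x$d) - 1))
}
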