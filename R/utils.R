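`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic C-locale sort for county identifiers.
csort <- function(x) sort(x, method = "radix")

# Locale-independent string comparison: TRUE iff x < y byte-wise.
str_less_c <- function(x, y) {
  if (x == y) return(FALSE)
  xi <- utf8ToInt(x)
  yi <- utf8ToInt(y)
  n <- min(length(xi), length(yi))
  d <- which(xi[seq_len(n)] != yi[seq_len(n)])
  if (length(d)) xi[d[1L]] < yi[d[1L]] else length(xi) < length(yi)
}

# Lexicographic order on sorted integer vectors; a strict prefix sorts first.
lex_less_idx <- function(a, b) {
  n <- min(length(a), length(b))
  if (n > 0L) {
    d <- which(a[seq_len(n)] != b[seq_len(n)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  length(a) < length(b)
}

# Deterministic per-replicate seed streams derived from one root seed, so
# replicate r is reproducible independently of evaluation order.
child_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
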