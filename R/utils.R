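# internal validation and hashing helpers

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    .stopf("'%s' must be a single finite number", name)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    .stopf("'%s' = %g is outside the admissible range %s%g, %g%s", name, x,
           if (allow_lower) "[" else "(", lower, upper,
           if (allow_upper) "]" else ")")
  invisible(x)
}

.check_count <- function(x, name, lower = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    .stopf("'%s' must be a single integer >= %d", name, lower)
  invisible(as.integer(x))
}

.check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stopf("'%s' must be TRUE or FALSE", name)
  invisible(x)
}

.set_seed <- function(seed) {
  if (!is.null(seed)) {
    .check_count(seed, "seed")
    set.seed(seed)
  }
  invisible(NULL)
}

# FNV-1a 32-bit hash of a deparsed R object; 16-bit splits keep xor and the
# modular multiplication exact in double precision
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    hi <- bitwXor(as.integer(h %/% 65536), as.integer(b %/% 65536))
    h <- hi * 65536 + lo
    hi <- h %/% 65536
    lo <- h %% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 2^32
  }
  sprintf("%08x", h)
}
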