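# internal helpers shared across modules

# user-facing errors (bad input, schema violations) get their own condition
# class so the command-line front-end can map them to exit code 1
.stopUser <- function(fmt, ...) {
  msg <- if (length(list(...))) sprintf(fmt, ...) else fmt
  stop(structure(class = c("targetAE_user_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# round half away from zero to integer (metrics are reported as integer
# percents; round() would round 0.5 to even)
.roundHalfUp <- function(x) floor(x + 0.5)

# derive a reproducible sub-seed (< 2^31) from a master seed and a stream name,
# so each synthetic table draws from its own stream and adding a table does not
# perturb the others
.substreamSeed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 31 + k) %% 1000003
  as.integer((as.double(seed) %% 65521 + 1) * 32749 + h) %% 2147483L + 1L
}

.checkFlag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    .stopUser("%s must be TRUE or FALSE", nm)
  x
}

.checkNumber <- function(x, nm, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    .stopUser("%s must be a number in [%s, %s]", nm, lo, hi)
  as.numeric(x)
}

.checkCount <- function(x, nm, lo = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x != as.integer(x))
    .stopUser("%s must be an integer >= %d", nm, lo)
  as.integer(x)
}
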