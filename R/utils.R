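# Internal helpers: keyed RNG streams and small formatting utilities.

#' @importFrom stats rnorm runif rlnorm median sd t.test p.adjust
#' @importFrom utils head
NULL

# Fold an arbitrary list of strings/numbers into a deterministic 31-bit seed.
# Polynomial rolling hash over UTF-8 bytes, mod the Mersenne prime 2^31 - 1,
# so derived seeds always fit an R integer.
mix_seed <- function(seed, ...) {
  parts <- vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                  character(1))
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    bytes <- utf8ToInt(paste0(p, "\x01"))
    for (b in bytes) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Evaluate expr under a local RNG seeded with `seed`, restoring global state.
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Render a numeric ratio column for reports: 4 decimals, NA -> "N.D."
format_ratio <- function(x) {
  out <- ifelse(is.na(x), "N.D.", sprintf("%.4f", x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
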