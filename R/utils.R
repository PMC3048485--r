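# Internal helpers shared across modules.

# Conversion constant: 1 e*Angstrom in Debye.
DEBYE_PER_E_ANGSTROM <- 4.80321

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stop_rbp <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "rbp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Fixed-precision number formatting for CLI output (6 significant digits,
# no scientific notation drift between runs).
fmt_num <- function(x) formatC(signif(x, 6), format = "g", digits = 6)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)
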