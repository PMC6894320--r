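#' @keywords internal
#' @importFrom ggplot2 .data
"_PACKAGE"

# Stable 31-bit hash of a character string; used to derive per-donor and
# per-pair RNG seeds so that adding a donor never perturbs another donor's
# random draws.
string_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

# Combine a base seed with a label into a seed below 2^31.
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) %% 2147483647 + string_hash(label)) %% 2147483647)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
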