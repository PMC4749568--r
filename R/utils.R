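#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a reproducible child seed from a root seed plus component keys.
# Independent components get independent streams, so adding neurites (a new
# key) never perturbs draws made under existing keys. Kept below 2^31.
child_seed <- function(root, ...) {
  m <- 2147483629
  h <- as.numeric(root %% m)
  for (k in list(...)) {
    if (is.character(k)) {
      k <- sum(utf8ToInt(k) * seq_along(utf8ToInt(k)))
    }
    h <- (h * 48271 + as.numeric(k) + 1) %% m
  }
  as.integer(h)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "sigold_config_error")
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x == floor(x)
}

is_prob <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x >= 0 && x <= 1
}
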