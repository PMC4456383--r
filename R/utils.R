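#' @importFrom rlang %||% abort warn .data
#' @import dplyr
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats var median rnorm rpois rbinom runif qnorm pnorm quantile
#'   lm lm.fit fisher.test setNames complete.cases pt p.adjust spline cor
NULL

# Evaluate `code` under a temporary RNG state so generators are pure
# functions of (arguments, seed) and never disturb the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv(), inherits = FALSE)
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# 32-bit modular multiply by the FNV prime, in doubles (no overflow).
fnv_mul <- function(h, p = 16777619) {
  lo <- h %% 65536
  hi <- h %/% 65536
  (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
}

fnv1a <- function(x) {
  h <- 2166136261
  for (b in utf8ToInt(x)) {
    low <- h %% 256  # xor only touches the low byte (b < 256)
    h <- fnv_mul(h - low + bitwXor(as.integer(low), as.integer(b)))
  }
  h
}

# Hierarchical seed derivation: one global seed plus a string key yields a
# reproducible per-component seed (FNV-1a, folded below 2^31).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  as.integer(fnv1a(key) %% 2147483647)
}

# FNV-1a hash of a string, as hex; used for config provenance stamps.
fnv1a_hex <- function(x) {
  h <- fnv1a(x)
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

check_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < lower || x > upper) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, lower, upper))
  }
  x
}

check_count <- function(x, name, lower = 1) {
  check_number(x, name, lower = lower)
  if (x != round(x)) abort(sprintf("`%s` must be a whole number", name))
  as.integer(x)
}

check_columns <- function(df, cols, name = deparse(substitute(df))) {
  if (!is.data.frame(df)) abort(sprintf("`%s` must be a data frame", name))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s", name,
                  paste(missing, collapse = ", ")))
  }
  invisible(df)
}
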