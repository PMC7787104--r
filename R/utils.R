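#' @importFrom stats dnorm integrate optim pnorm qnorm rexp rnorm runif sd
#' @importFrom utils head read.table write.table
NULL

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used for content-derived DAG node ids; stability matters, cryptographic
# strength does not.
fnv1a_hex <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  prime_lo <- 403      # 16777619 = 256 * 65536 + 403
  prime_hi <- 256
  for (b in bytes) {
    # xor only touches the low byte (b < 256); keeps h a double-safe 32-bit value
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), as.integer(b))
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * prime_lo + ((lo * prime_hi + hi * prime_lo) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Canonical serialization for hashing: names sorted recursively, numerics
# rounded to 10 significant digits so that re-reading from text round-trips.
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      v <- lapply(v, sort_rec)
      if (!is.null(names(v)) && any(nzchar(names(v)))) v <- v[order(names(v))]
    } else if (is.double(v)) {
      v <- signif(v, 10)
    }
    v
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = 10, null = "null"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

vapply_chr <- function(x, f) vapply(x, f, character(1))
vapply_num <- function(x, f) vapply(x, f, numeric(1))
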