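#' FNV-1a 64-bit hash of a byte string
#'
#' Pure-R implementation of the Fowler-Noll-Vo 1a hash (64-bit variant,
#' offset basis 0xcbf29ce484222325, prime 0x100000001b3), operating on
#' 16-bit limbs so all arithmetic stays exact in doubles. This is the
#' deterministic, platform-independent hash behind the default producer
#' partitioning strategy.
#'
#' @param bytes a raw vector (or a character scalar, converted with
#'   [charToRaw()]).
#' @return the hash as four 16-bit limbs, least significant first
#'   (numeric vector of length 4). Use [fnv1a64_hex()] for a printable
#'   form or [fnv1a64_mod()] to reduce modulo a small integer.
#' @keywords internal
fnv1a64 <- function(bytes) {
  bytes <- as_bytes(bytes)
  h <- c(0x2325, 0x8422, 0x9ce4, 0xcbf2)
  p <- c(0x01b3, 0x0000, 0x0100, 0x0000)
  for (b in as.integer(bytes)) {
    h[1] <- bitwXor(as.integer(h[1]), b)
    r <- numeric(4L)
    for (i in 1:4) {
      if (h[i] == 0) next
      for (j in 1:(5L - i)) {
        k <- i + j - 1L
        r[k] <- r[k] + h[i] * p[j]
      }
    }
    for (k in 1:3) {
      carry <- r[k] %/% 65536
      r[k] <- r[k] %% 65536
      r[k + 1L] <- r[k + 1L] + carry
    }
    r[4L] <- r[4L] %% 65536
    h <- r
  }
  h
}

#' @rdname fnv1a64
#' @keywords internal
fnv1a64_hex <- function(bytes) {
  paste0(sprintf("%04x", rev(fnv1a64(bytes))), collapse = "")
}

#' @param n a positive integer modulus.
#' @rdname fnv1a64
#' @keywords internal
fnv1a64_mod <- function(bytes, n) {
  h <- fnv1a64(bytes)
  r <- 0
  for (i in 4:1) r <- (r * 65536 + h[i]) %% n
  as.integer(r)
}

# Coerce key material to raw bytes. NULL stays NULL (absent key/value).
as_bytes <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.raw(x)) return(x)
  if (is.character(x) && length(x) == 1L) return(charToRaw(x))
  stop("expected a raw vector, a single character string, or NULL")
}

# Hex fingerprint of a raw vector, usable as a named-list key even when the
# bytes contain NULs (rawToChar would refuse those).
bytes_id <- function(bytes) paste(as.character(bytes), collapse = "")
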