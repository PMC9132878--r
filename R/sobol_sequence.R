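## Quasi-random Sobol sequence generation.
##
## Digital (base-2) Sobol points via the Gray-code construction, with
## primitive polynomials and initial direction numbers from the Joe-Kuo D(6)
## table (first 31 dimensions; dimension 1 is the van der Corput sequence).
## 30 output bits are used so all intermediate integers stay within R's
## 32-bit signed range.

## Joe-Kuo table: polynomial degree s, interior coefficient bits a, and
## initial direction numbers m for dimensions 2..31.
.sobol_s <- c(1L, 2L, 3L, 3L, 4L, 4L, 5L, 5L, 5L, 5L, 5L, 5L, 6L, 6L, 6L, 6L,
              6L, 6L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L, 7L)
.sobol_a <- c(0L, 1L, 1L, 2L, 1L, 4L, 2L, 4L, 7L, 11L, 13L, 14L, 1L, 13L, 16L,
              19L, 22L, 25L, 1L, 4L, 7L, 8L, 14L, 19L, 21L, 28L, 31L, 32L, 37L, 41L)
.sobol_m <- list(
  c(1), c(1, 3), c(1, 3, 1), c(1, 1, 1), c(1, 1, 3, 3), c(1, 3, 5, 13),
  c(1, 1, 5, 5, 17), c(1, 1, 5, 5, 5), c(1, 1, 7, 11, 19), c(1, 1, 5, 1, 1),
  c(1, 1, 1, 3, 11), c(1, 3, 5, 5, 31), c(1, 3, 3, 9, 7, 49),
  c(1, 1, 1, 15, 21, 21), c(1, 3, 1, 13, 27, 49), c(1, 1, 1, 15, 7, 5),
  c(1, 3, 1, 15, 13, 25), c(1, 1, 5, 5, 19, 61), c(1, 3, 7, 11, 23, 15, 103),
  c(1, 3, 7, 13, 13, 15, 69), c(1, 1, 3, 13, 7, 35, 63),
  c(1, 3, 5, 9, 1, 25, 53), c(1, 3, 1, 13, 9, 35, 107),
  c(1, 3, 1, 5, 27, 61, 31), c(1, 1, 5, 11, 19, 41, 61),
  c(1, 3, 5, 3, 3, 13, 69), c(1, 1, 7, 13, 1, 19, 1),
  c(1, 3, 7, 5, 13, 19, 59), c(1, 1, 3, 9, 25, 29, 41),
  c(1, 3, 5, 13, 23, 1, 55)
)

.SOBOL_BITS <- 30L

## direction-number vectors (length .SOBOL_BITS) for one dimension
sobol_directions <- function(dim) {
  L <- .SOBOL_BITS
  v <- integer(L)
  if (dim == 1) {
    v <- bitwShiftL(1L, L - seq_len(L))
    return(v)
  }
  s <- .sobol_s[dim - 1]
  a <- .sobol_a[dim - 1]
  m <- .sobol_m[[dim - 1]]
  for (k in seq_len(min(s, L))) {
    v[k] <- bitwShiftL(as.integer(m[k]), L - k)
  }
  if (L > s) {
    for (k in (s + 1):L) {
      vk <- bitwXor(v[k - s], bitwShiftR(v[k - s], s))
      if (s > 1) {
        for (i in seq_len(s - 1)) {
          if (bitwAnd(bitwShiftR(a, s - 1 - i), 1L) == 1L) {
            vk <- bitwXor(vk, v[k - i])
          }
        }
      }
      v[k] <- vk
    }
  }
  v
}

#' Sobol low-discrepancy sequence
#'
#' Generates points of the (unscrambled) Sobol sequence in the unit
#' hypercube, including the initial zero point, using Joe-Kuo direction
#' numbers.  The sequence is deterministic: the same `(n, dim, skip)` always
#' yields the same matrix.
#'
#' @param n number of points.
#' @param dim dimension (1 to 31).
#' @param skip number of initial points to skip.
#' @return an `n x dim` matrix with entries in `[0, 1)`.
#' @export
sobol_sequence <- function(n, dim, skip = 0) {
  if (n < 1 || dim < 1 || dim > 31) {
    abort_validation("sobol_sequence: need n >= 1 and 1 <= dim <= 31")
  }
  if (n + skip > 2^.SOBOL_BITS) {
    abort_validation("sobol_sequence: sequence length exceeds generator period")
  }
  V <- vapply(seq_len(dim), sobol_directions, integer(.SOBOL_BITS))
  out <- matrix(0, n, dim)
  x <- integer(dim) # current integer state (point 0 = origin)
  total <- n + skip
  denom <- 2^.SOBOL_BITS
  row <- 0L
  if (skip == 0L) {
    out[1, ] <- 0
    row <- 1L
  }
  if (total > 1) {
    for (i in seq_len(total - 1)) {
      ## Gray-code step: flip direction c = position of lowest zero bit of i-1
      c <- 1L
      im1 <- i - 1L
      while (bitwAnd(im1, 1L) == 1L) {
        im1 <- bitwShiftR(im1, 1L)
        c <- c + 1L
      }
      x <- bitwXor(x, V[c, ])
      if (i >= skip) {
        row <- row + 1L
        if (row > n) break
        out[row, ] <- x / denom
      }
    }
  }
  out
}
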