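#' Fixed-point number formats
#'
#' Describes a fixed-point lattice by word length, fraction length and
#' signedness: representable values are `raw * 2^-frac_bits` with `raw`
#' ranging over the signed or unsigned integer range of `total_bits` bits.
#' These emulate the storage formats of a digital (FPGA-style) implementation
#' so that quantised training can be exercised and its accuracy cost measured.
#'
#' @param total_bits Word length in bits (`>= frac_bits`).
#' @param frac_bits Fraction length in bits (`>= 0`).
#' @param signed Logical; two's-complement signed range if `TRUE`.
#' @return An `fp_format` object with fields `total_bits`, `frac_bits`,
#'   `signed`, and the raw-integer bounds `raw_min`, `raw_max`.
#' @examples
#' fp_format(17, 12, signed = TRUE)   # synaptic weight storage
#' @export
fp_format <- function(total_bits, frac_bits, signed = TRUE) {
  stopifnot(total_bits >= frac_bits, frac_bits >= 0, total_bits >= 1)
  if (signed) {
    raw_min <- -2^(total_bits - 1)
    raw_max <- 2^(total_bits - 1) - 1
  } else {
    raw_min <- 0
    raw_max <- 2^total_bits - 1
  }
  structure(list(total_bits = as.integer(total_bits),
                 frac_bits = as.integer(frac_bits),
                 signed = isTRUE(signed),
                 raw_min = raw_min, raw_max = raw_max),
            class = "fp_format")
}

#' @export
print.fp_format <- function(x, ...) {
  cat(sprintf("<fp_format> %s %d-bit, %d fractional (range [%g, %g])\n",
              if (x$signed) "signed" else "unsigned",
              x$total_bits, x$frac_bits,
              x$raw_min * 2^-x$frac_bits, x$raw_max * 2^-x$frac_bits))
  invisible(x)
}

#' Default hardware storage formats
#'
#' The default per-variable storage formats of the emulated digital design:
#' synaptic weights `w` signed 17-bit with 12 fractional bits, S-PSPs `e`
#' unsigned 11-bit with 6 fractional bits, membrane potentials `v` signed
#' 9-bit with 3 fractional bits.
#'
#' @return Named list of [fp_format()] objects with elements `w`, `e`, `v`.
#' @examples
#' fp_defaults()$w
#' @export
fp_defaults <- function() {
  list(w = fp_format(17, 12, signed = TRUE),
       e = fp_format(11, 6, signed = FALSE),
       v = fp_format(9, 3, signed = TRUE))
}

#' Quantize real values onto a fixed-point lattice
#'
#' Rounds to the nearest lattice point (ties to even, the IEEE default) and
#' saturates at the format's representable range; saturation replaces
#' overflow, as in hardware. Round-trips of values already on the lattice are
#' exact.
#'
#' @param x Numeric vector/matrix of real values.
#' @param fmt An [fp_format()].
#' @return An `fp_value`: list with `raw` (integer-valued numeric, same shape
#'   as `x`) and `fmt`.
#' @examples
#' q <- quantize(0.3, fp_format(11, 6, signed = FALSE))
#' q$raw            # 19: round(0.3 * 64)
#' fp_real(q)       # 0.296875
#' @export
quantize <- function(x, fmt) {
  stopifnot(inherits(fmt, "fp_format"))
  raw <- round(x * 2^fmt$frac_bits)      # round-half-to-even
  raw <- pmin(pmax(raw, fmt$raw_min), fmt$raw_max)
  structure(list(raw = raw, fmt = fmt), class = "fp_value")
}

#' @rdname quantize
#' @param raw Integer-valued numeric already on the lattice.
#' @export
fp_from_raw <- function(raw, fmt) {
  stopifnot(inherits(fmt, "fp_format"))
  if (any(raw < fmt$raw_min | raw > fmt$raw_max)) {
    stop("raw value outside the format's integer range", call. = FALSE)
  }
  structure(list(raw = raw, fmt = fmt), class = "fp_value")
}

#' @rdname quantize
#' @param q An `fp_value`.
#' @export
fp_real <- function(q) {
  stopifnot(inherits(q, "fp_value"))
  q$raw * 2^-q$fmt$frac_bits
}

#' @export
print.fp_value <- function(x, ...) {
  cat(sprintf("<fp_value> %d value(s) in %s Q%d.%d\n", length(x$raw),
              if (x$fmt$signed) "signed" else "unsigned",
              x$fmt$total_bits - x$fmt$frac_bits, x$fmt$frac_bits))
  print(utils::head(fp_real(x), 10L))
  invisible(x)
}

# Truncating (floor) arithmetic right shift on integer-valued numerics,
# identical to a two's-complement arithmetic shift in hardware.
fp_shift_right <- function(raw, k) floor(raw / 2^k)

#' Shift-based exponential decay
#'
#' Multiplies a quantised value by `(1 - 1/tau)` with `tau = 2^tau_power`
#' exactly as shift-based hardware does: `raw <- raw - (raw >> tau_power)`,
#' the shift truncating (arithmetic). Bit-exact and reproducible; this is the
#' decay primitive of the fixed-point membrane/synapse/S-PSP recurrences.
#'
#' @param q An `fp_value`.
#' @param tau_power Non-negative integer; the decay constant is
#'   `2^tau_power` time steps.
#' @return The decayed `fp_value` (same format).
#' @examples
#' q <- fp_from_raw(64, fp_format(11, 6, signed = FALSE))
#' shift_decay(q, 2)$raw   # 64 - 16 = 48
#' @export
shift_decay <- function(q, tau_power) {
  stopifnot(inherits(q, "fp_value"), tau_power >= 0)
  raw <- q$raw - fp_shift_right(q$raw, tau_power)
  fp_from_raw(raw, q$fmt)
}

#' Signed power-of-2 multiplication by arithmetic shift
#'
#' Multiplies a quantised value by `sign * 2^m` the way the shift-based
#' error-feedback datapath does: left shift by `m`, negate (two's complement)
#' when the feedback entry is negative, emit zero when the entry is masked
#' out (`sign = 0`). Saturates at the format range.
#'
#' @param q An `fp_value`.
#' @param m Non-negative integer shift amount.
#' @param sign One of -1, 0, 1.
#' @return The shifted `fp_value` (same format).
#' @examples
#' q <- fp_from_raw(5, fp_format(17, 12))
#' shift_mul(q, 2, -1)$raw  # -20
#' @export
shift_mul <- function(q, m, sign) {
  stopifnot(inherits(q, "fp_value"), m >= 0, sign %in% c(-1, 0, 1))
  raw <- if (sign == 0) q$raw * 0 else sign * q$raw * 2^m
  raw <- pmin(pmax(raw, q$fmt$raw_min), q$fmt$raw_max)
  fp_from_raw(raw, q$fmt)
}
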