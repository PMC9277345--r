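#' s16.23 fixed-point number system
#'
#' The node's ODE pipelines compute on a 40-bit signed fixed-point data type
#' with 16 integer and 23 fractional bits (s16.23). A value `x` is represented
#' by the integer `raw = round(x * 2^23)` (round-to-nearest-even), restricted
#' to `[-2^39, 2^39 - 1]`, i.e. values in `[-65536, 65536 - 2^-23]`. Raw
#' values are carried in R doubles, which represent every 40-bit integer
#' exactly.
#'
#' All arithmetic saturates instead of wrapping on overflow; saturation events
#' are counted on the result's `"saturations"` attribute so a simulation can
#' assert that none occurred. Multiplication keeps the full-precision integer
#' product and truncates toward minus infinity (arithmetic right shift by 23),
#' the cheapest DSP datapath behaviour.
#'
#' @param x numeric vector of real values to encode.
#' @param raw,a,b numeric vectors of raw s16.23 values (as produced by
#'   [fx_encode()]); binary operations recycle the shorter operand.
#' @return `fx_encode()` and the arithmetic functions return raw values;
#'   `fx_decode()` returns real values (`raw * 2^-23`, exact in double
#'   precision). Arithmetic results carry an integer `"saturations"`
#'   attribute.
#' @examples
#' fx_encode(1.0)                      # 8388608 = 2^23
#' fx_decode(fx_mul(fx_encode(2), fx_encode(3)))
#' @name fixedpoint
NULL

#' @rdname fixedpoint
#' @export
fx_encode <- function(x) {
  if (any(!is.finite(x))) stop("fx_encode: all values must be finite")
  fx_encode_cpp(as.numeric(x))
}

#' @rdname fixedpoint
#' @export
fx_decode <- function(raw) fx_decode_cpp(as.numeric(raw))

#' @rdname fixedpoint
#' @export
fx_add <- function(a, b) fx_add_cpp(as.numeric(a), as.numeric(b))

#' @rdname fixedpoint
#' @export
fx_sub <- function(a, b) fx_sub_cpp(as.numeric(a), as.numeric(b))

#' @rdname fixedpoint
#' @export
fx_mul <- function(a, b) fx_mul_cpp(as.numeric(a), as.numeric(b))

#' @rdname fixedpoint
#' @export
fx_info <- function() {
  tibble::tibble(
    int_bits = 16L, frac_bits = 23L, total_bits = 40L,
    raw_min = -2^39, raw_max = 2^39 - 1,
    value_min = -65536, value_max = 65536 - 2^-23,
    resolution = 2^-23
  )
}
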