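# Unit handling at the configuration boundary. Scenario files carry explicit
# unit suffixes ("29 ug/s", "7.8 m", "0.01 cm/s", "1 km", "260 nm"); all
# internal computation is SI (g, m, s, K, kg/m3). Bare numbers are taken as SI.

.unit_table <- list(
  "g/s" = c("g/s" = 1, "mg/s" = 1e-3, "ug/s" = 1e-6, "kg/s" = 1e3,
            "g/h" = 1 / 3600, "mg/min" = 1e-3 / 60, "mg/h" = 1e-3 / 3600),
  "m" = c("m" = 1, "km" = 1e3, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
          "nm" = 1e-9),
  "m/s" = c("m/s" = 1, "cm/s" = 1e-2, "mm/s" = 1e-3, "km/h" = 1 / 3.6),
  "kg/m3" = c("kg/m3" = 1, "g/cm3" = 1e3),
  "K" = c("K" = 1)
)

#' Parse a physical quantity with unit suffix
#'
#' Converts strings such as `"29 ug/s"`, `"1 km"`, `"0.01 cm/s"`, `"260 nm"`,
#' `"940 kg/m3"` or `"15 C"` to SI (g/s, m, m/s, kg/m3, K). Bare numerics are
#' assumed to already be SI.
#'
#' @param x a number, or a string `"<value> <unit>"`.
#' @param dimension target dimension: `"g/s"`, `"m"`, `"m/s"`, `"kg/m3"`
#'   or `"K"`.
#' @return Numeric value in SI units.
#' @export
parse_quantity <- function(x, dimension) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1]]
  if (length(m) != 3L || is.na(suppressWarnings(as.numeric(m[2])))) {
    stop("cannot parse quantity: '", x, "'", call. = FALSE)
  }
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  if (dimension == "K") {
    return(switch(unit,
                  "K" = val,
                  "C" = , "degC" = val + 273.15,
                  stop("unknown temperature unit: ", unit, call. = FALSE)))
  }
  conv <- .unit_table[[dimension]]
  if (is.null(conv) || is.na(conv[unit])) {
    stop("unknown unit '", unit, "' for dimension ", dimension, call. = FALSE)
  }
  val * conv[[unit]]
}

# canonical serialization: SI value + SI unit suffix, so that
# parse(format(parse(x))) == parse(x)
.format_quantity <- function(value, dimension) {
  unit <- switch(dimension, "g/s" = "g/s", "m" = "m", "m/s" = "m/s",
                 "kg/m3" = "kg/m3", "K" = "K")
  paste(format(value, digits = 15), unit)
}
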