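#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
NULL

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in financial reporting (base [round()] rounds ties to
#' even). All printed currency in this package is rounded this way.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, i.e. cents).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(2.675)      # 2.68, not 2.67
#' round_half_up(111.835)    # 111.84
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  trunc(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) * sign(x) / p
}

# currency: always cents
round_cents <- function(x) round_half_up(x, 2)

# "$1,320,304.68" / "-$529,115.57"
fmt_cad <- function(x) {
  paste0(ifelse(x < 0, "-$", "$"),
         formatC(abs(round_cents(x)), format = "f", digits = 2, big.mark = ","))
}

stop_invalid <- function(field, msg) {
  abort(paste0("Invalid parameter `", field, "`: ", msg),
        class = "vomscba_invalid_parameter")
}

check_nonneg <- function(value, field) {
  if (!is.numeric(value) || any(!is.finite(value)) || any(value < 0)) {
    stop_invalid(field, "must be a non-negative finite number")
  }
  invisible(value)
}

check_prob <- function(value, field) {
  if (!is.numeric(value) || any(!is.finite(value)) ||
      any(value < 0) || any(value > 1)) {
    stop_invalid(field, "must be a probability in [0, 1]")
  }
  invisible(value)
}

check_range <- function(range, point, field) {
  if (length(range) != 2 || any(!is.finite(range)) || range[1] > range[2]) {
    stop_invalid(field, "must be an ordered (low, high) pair")
  }
  if (point < range[1] || point > range[2]) {
    stop_invalid(field, sprintf("range [%s, %s] must contain the point value %s",
                                range[1], range[2], point))
  }
  invisible(range)
}

# simple pipe-free markdown table used by the report writers
render_md_table <- function(df) {
  df[] <- lapply(df, function(col) {
    if (is.numeric(col)) formatC(col, format = "fg", big.mark = "", digits = 15)
    else as.character(col)
  })
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1L, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  paste(c(header, sep, rows), collapse = "\n")
}
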