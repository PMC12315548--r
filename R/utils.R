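#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn inform .data
#' @importFrom dplyr %>%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n
#' @importFrom Rcpp sourceCpp
#' @useDynLib secretrain, .registration = TRUE
NULL

stop_secretrain <- function(msg, class) {
  rlang::abort(msg, class = c(paste0("secretrain_", class), "secretrain_error"))
}

# Validate that `args` only uses known parameter names; used by all config
# constructors so that misspelled keys fail loudly.
check_known_keys <- function(args, known, where) {
  extra <- setdiff(names(args), known)
  if (length(extra) > 0) {
    stop_secretrain(
      sprintf("unknown %s parameter(s): %s", where,
              paste(extra, collapse = ", ")),
      "config_error")
  }
  invisible(args)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x >= lower && x <= upper && (!integer || x == round(x))
  if (!ok) {
    stop_secretrain(
      sprintf("`%s` must be a %s in [%s, %s], got %s", name,
              if (integer) "whole number" else "number",
              format(lower), format(upper), paste(format(x), collapse = ",")),
      "config_error")
  }
  invisible(x)
}

# Round half up to `digits` decimals (commercial rounding), so that e.g.
# 99.015 prints as 99.02 rather than banker's-rounded 99.01.
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

seq_codes <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], AA_ALPHABET)
}
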