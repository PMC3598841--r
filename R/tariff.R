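#' Load an EQ-5D-3L value set (tariff)
#'
#' A tariff maps a five-dimension, three-level EQ-5D profile to a single
#' health utility. The tariff file is a two-column `term,value` table with
#' the decrements of the additive time-trade-off model: a `constant`
#' subtracted for any departure from full health, per-dimension decrements
#' for levels 2 and 3 (`MO2`, `MO3`, `SC2`, ..., `AD3`), and an `N3` term
#' subtracted once if any dimension is at level 3.
#'
#' Two value sets are shipped with the package: the UK time-trade-off
#' tariff (`"uk_tto"`, the model's default) and the Dutch time-trade-off
#' tariff (`"nl_tto"`, used in sensitivity analysis). The loader checks the
#' anchor property that the full-health profile 11111 evaluates to exactly 1.
#'
#' @param which `"uk_tto"`, `"nl_tto"`, or a path to a `term,value` file.
#' @return An object of class `eq5d_tariff`: a named numeric vector of
#'   coefficients.
#' @export
#' @examples
#' tar <- read_tariff("uk_tto")
#' eq5d_utility(c(1, 1, 1, 1, 1), tar)
read_tariff <- function(which = "uk_tto") {
  path <- if (which %in% c("uk_tto", "nl_tto")) {
    system.file("extdata", paste0("tariff_", which, ".csv"),
                package = "fabrycea", mustWork = TRUE)
  } else {
    which
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("term", "value") %in% names(tab))) {
    stop("tariff file must have columns 'term' and 'value'")
  }
  coefs <- stats::setNames(tab$value, tab$term)
  need <- c("constant", paste0(rep(c("MO", "SC", "UA", "PD", "AD"), each = 2),
                               2:3), "N3")
  missing <- setdiff(need, names(coefs))
  if (length(missing)) {
    stop("tariff file is missing term(s): ", paste(missing, collapse = ", "))
  }
  obj <- structure(coefs, class = "eq5d_tariff",
                   source = if (which %in% c("uk_tto", "nl_tto")) which else path)
  u_full <- eq5d_utility(c(1, 1, 1, 1, 1), obj)
  if (abs(u_full - 1) > 1e-12) {
    stop("invalid tariff: full-health profile does not evaluate to 1.0")
  }
  obj
}

#' Evaluate an EQ-5D-3L profile under a tariff
#'
#' @param profile Integer vector of length 5 (mobility, self-care, usual
#'   activities, pain/discomfort, anxiety/depression), each in 1:3.
#' @param tariff An `eq5d_tariff` from [read_tariff()].
#' @return The health utility (1 for full health; can be negative for
#'   severe profiles).
#' @export
eq5d_utility <- function(profile, tariff) {
  if (length(profile) != 5L) stop("an EQ-5D profile has exactly 5 dimensions")
  profile <- as.integer(profile)
  if (anyNA(profile) || any(profile < 1L | profile > 3L)) {
    stop("EQ-5D levels must be integers in {1, 2, 3}")
  }
  dims <- c("MO", "SC", "UA", "PD", "AD")
  u <- 1
  if (any(profile > 1L)) {
    u <- u - tariff[["constant"]]
    lev2 <- dims[profile == 2L]
    lev3 <- dims[profile == 3L]
    if (length(lev2)) u <- u - sum(tariff[paste0(lev2, "2")])
    if (length(lev3)) u <- u - sum(tariff[paste0(lev3, "3")])
    if (length(lev3)) u <- u - tariff[["N3"]]
  }
  unname(u)
}

#' @export
print.eq5d_tariff <- function(x, ...) {
  cat("EQ-5D-3L time-trade-off tariff (", attr(x, "source"), ")\n", sep = "")
  print(unclass(x))
  invisible(x)
}
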