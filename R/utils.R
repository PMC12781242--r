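# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

#' @importFrom data.table fread fwrite :=
#' @importFrom stats pnorm rlnorm runif sd
#' @importFrom utils head
NULL

# Classed conditions so callers can distinguish failure modes programmatically.
# All errors raised by this package carry the "ginidimorph_error" class plus a
# specific subclass (gd_format_error, gd_dimension_error, gd_domain_error,
# gd_identifier_error, gd_contract_error, gd_cohort_error, gd_io_error).
gd_abort <- function(message, class) {
  stop(errorCondition(message, class = c(class, "ginidimorph_error")))
}

# Round half away from zero (so 2.25 -> 2.3), matching how the reported
# male/female sample ratios are printed.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Drop the Ensembl version suffix ("ENSG00000123456.7" -> "ENSG00000123456").
# Idempotent: stripping twice is the same as stripping once.
strip_gene_version <- function(ids) {
  sub("\\.[0-9]+$", "", ids)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric vector validation common to the Gini family.
check_nonnegative <- function(x, what = "values") {
  if (!is.numeric(x)) {
    gd_abort(sprintf("%s must be numeric", what), "gd_domain_error")
  }
  if (length(x) && (anyNA(x) || any(!is.finite(x)))) {
    gd_abort(sprintf("%s contain missing or non-finite entries", what),
             "gd_domain_error")
  }
  if (length(x) && any(x < 0)) {
    gd_abort(sprintf("%s contain negative entries", what), "gd_domain_error")
  }
  invisible(x)
}
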