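#' Microscopic rate constants of the lactate oxidase scheme
#'
#' Bundles the seven mass-action rate constants of the two-half-reaction
#' mechanism: substrate binding (`k1`, `k2`), FMN reduction by bound lactate
#' (`k3`) and its reverse (`k4`), pyruvate release (`k5`) and re-binding
#' (`k6`), and second-order FMN re-oxidation by O2 (`k7`). Units are molar
#' and seconds throughout: `k1`, `k6`, `k7` are per-molar per-second, the
#' rest per-second.
#'
#' `k4` and `k6` default to zero: the concentration dependence of the
#' observed reduction rate extrapolates through the origin, so reverse FMN
#' oxidation by bound pyruvate is not detectable, and product re-binding has
#' never been quantified. Both remain settable for sensitivity analyses.
#' Binding defaults are rapid-equilibrium: `k1 = 1e8` per-molar per-second
#' (near diffusion limit) with `k2` chosen from the substrate dissociation
#' constant so that the fast stopped-flow phase is reduction-limited.
#'
#' @param k1 lactate association rate constant (M^-1 s^-1)
#' @param k2 lactate dissociation rate constant (s^-1)
#' @param k3 FMN reduction (hydride transfer) rate constant (s^-1)
#' @param k4 reverse FMN oxidation by bound pyruvate (s^-1), default 0
#' @param k5 pyruvate release rate constant (s^-1)
#' @param k6 pyruvate re-association rate constant (M^-1 s^-1), default 0
#' @param k7 FMN re-oxidation by O2, second order (M^-1 s^-1)
#' @param kd substrate dissociation constant (M); used to derive
#'   `k2 = kd * k1` when `k2` is not given
#' @param label optional variant label (e.g. "wild-type", "Y215F")
#' @param ph optional reaction pH tag
#' @return an object of class `lox_rates` (a named list)
#' @examples
#' rates_wt <- lox_rates(k3 = 270, k5 = 141, k7 = 1.8e6, kd = 1.0e-3,
#'                       label = "wild-type", ph = 6.5)
#' @export
lox_rates <- function(k1 = 1e8, k2 = NULL, k3, k4 = 0, k5, k6 = 0, k7,
                      kd = NULL, label = NA_character_, ph = NA_real_) {
  if (is.null(k2)) {
    if (is.null(kd))
      stop_invalid_input("supply either `k2` or the dissociation constant `kd`")
    check_nonnegative(kd, "kd")
    k2 <- kd * k1
  }
  vals <- list(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7)
  for (nm in names(vals)) check_nonnegative(vals[[nm]], nm)
  structure(c(vals, list(label = label, ph = ph)), class = "lox_rates")
}

#' @param x a `lox_rates` object
#' @param ... unused
#' @rdname lox_rates
#' @export
print.lox_rates <- function(x, ...) {
  cat(sprintf("<lox_rates> %s (pH %s)\n",
              ifelse(is.na(x$label), "unlabelled", x$label),
              ifelse(is.na(x$ph), "?", format(x$ph))))
  cat(sprintf("  k1 = %.3g /M/s  k2 = %.3g /s  (Kd = %.3g M)\n",
              x$k1, x$k2, if (x$k1 > 0) x$k2 / x$k1 else NA_real_))
  cat(sprintf("  k3 = %.3g /s  k4 = %.3g /s  k5 = %.3g /s  k6 = %.3g /M/s\n",
              x$k3, x$k4, x$k5, x$k6))
  cat(sprintf("  k7 = %.3g /M/s\n", x$k7))
  invisible(x)
}

rate_fields <- c("k1", "k2", "k3", "k4", "k5", "k6", "k7")

rate_units <- c(k1 = "per_M_per_s", k2 = "per_s", k3 = "per_s", k4 = "per_s",
                k5 = "per_s", k6 = "per_M_per_s", k7 = "per_M_per_s")

#' Serialize rate constants to a flat key-value document
#'
#' Writes (or reads back) a JSON or YAML document with unit-annotated keys
#' (`k1_per_M_per_s`, `k3_per_s`, ...), the variant label and the pH tag.
#' The format is inferred from the file extension.
#'
#' @param rates a [lox_rates()] object
#' @param path file path ending in `.json`, `.yaml` or `.yml`
#' @return `read_lox_rates()` returns a [lox_rates()] object.
#' @export
write_lox_rates <- function(rates, path) {
  stopifnot(inherits(rates, "lox_rates"))
  doc <- stats::setNames(
    as.list(unlist(rates[rate_fields])),
    paste0(rate_fields, "_", rate_units[rate_fields]))
  doc$label <- rates$label
  doc$ph <- rates$ph
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(doc, path)
  }
  invisible(path)
}

#' @rdname write_lox_rates
#' @export
read_lox_rates <- function(path) {
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  expected <- paste0(rate_fields, "_", rate_units[rate_fields])
  missing <- setdiff(expected, names(doc))
  if (length(missing) > 0)
    lox_stop(paste0("rate document is missing keys: ",
                    paste(missing, collapse = ", ")), "lox_parse_error")
  extra <- setdiff(names(doc), c(expected, "label", "ph"))
  if (length(extra) > 0)
    lox_stop(paste0("rate document has unknown keys: ",
                    paste(extra, collapse = ", ")), "lox_parse_error")
  vals <- stats::setNames(as.numeric(doc[expected]), rate_fields)
  lox_rates(k1 = vals[["k1"]], k2 = vals[["k2"]], k3 = vals[["k3"]],
            k4 = vals[["k4"]], k5 = vals[["k5"]], k6 = vals[["k6"]],
            k7 = vals[["k7"]],
            label = if (is.null(doc$label)) NA_character_ else doc$label,
            ph = if (is.null(doc$ph)) NA_real_ else as.numeric(doc$ph))
}
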