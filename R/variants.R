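#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data
NULL

VARIANT_COLUMNS <- c(
  "name", "peak_density_pA_per_pF", "v_half_act_mV", "k_act_mV",
  "v_half_inact_mV", "k_inact_mV", "persistent_frac", "tau_rec_ms",
  "tau_inact_ms", "e_na_mV", "non_inactivating"
)

#' Construct a validated variant parameter set
#'
#' One row of the per-variant gating parameterization: the experimentally
#' fitted midpoints and peak density, plus the kinetic and floor parameters
#' that complete a single-gate (m1h1) Hodgkin-Huxley model of the variant.
#'
#' @param name Variant label, e.g. `"WT"` or `"N1662D"`.
#' @param peak_density_pA_per_pF Inward peak current density at -10 mV
#'   (positive magnitude, pA/pF).
#' @param v_half_act_mV,k_act_mV Activation midpoint and slope (mV; k > 0).
#' @param v_half_inact_mV,k_inact_mV Inactivation midpoint and slope (mV; k > 0).
#' @param persistent_frac Non-inactivating floor of the h gate, in \[0, 1\].
#' @param tau_rec_ms Recovery time constant at -120 mV (ms, > 0).
#' @param tau_inact_ms Inactivation time constant at -10 mV (ms, > 0).
#' @param e_na_mV Sodium reversal potential (mV).
#' @param non_inactivating Flag; must equal `persistent_frac >= 0.5`.
#' @return An object of class `variant_params` (a named list).
#' @export
variant_params <- function(name,
                           peak_density_pA_per_pF,
                           v_half_act_mV, k_act_mV = 6,
                           v_half_inact_mV, k_inact_mV = 6,
                           persistent_frac = 0,
                           tau_rec_ms,
                           tau_inact_ms = 1.5,
                           e_na_mV = 65,
                           non_inactivating = persistent_frac >= 0.5) {
  p <- list(
    name = as.character(name),
    peak_density_pA_per_pF = as.numeric(peak_density_pA_per_pF),
    v_half_act_mV = as.numeric(v_half_act_mV),
    k_act_mV = as.numeric(k_act_mV),
    v_half_inact_mV = as.numeric(v_half_inact_mV),
    k_inact_mV = as.numeric(k_inact_mV),
    persistent_frac = as.numeric(persistent_frac),
    tau_rec_ms = as.numeric(tau_rec_ms),
    tau_inact_ms = as.numeric(tau_inact_ms),
    e_na_mV = as.numeric(e_na_mV),
    non_inactivating = as.logical(non_inactivating)
  )
  validate_variant_params(p)
  structure(p, class = "variant_params")
}

validate_variant_params <- function(p) {
  bad <- function(msg) stop("variant '", p$name, "': ", msg, call. = FALSE)
  num <- p[setdiff(VARIANT_COLUMNS, c("name", "non_inactivating"))]
  if (any(!vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x), logical(1)))) {
    bad("all numeric fields must be single finite numbers")
  }
  if (p$peak_density_pA_per_pF <= 0) bad("peak_density must be > 0")
  if (p$k_act_mV <= 0) bad("k_act_mV must be > 0")
  if (p$k_inact_mV <= 0) bad("k_inact_mV must be > 0")
  if (p$persistent_frac < 0 || p$persistent_frac > 1) {
    bad("persistent_frac must lie in [0, 1]")
  }
  if (p$tau_rec_ms <= 0) bad("tau_rec_ms must be > 0")
  if (p$tau_inact_ms <= 0) bad("tau_inact_ms must be > 0")
  if (is.na(p$non_inactivating)) bad("non_inactivating must be TRUE or FALSE")
  if (p$non_inactivating != (p$persistent_frac >= 0.5)) {
    bad("non_inactivating must equal persistent_frac >= 0.5")
  }
  invisible(p)
}

#' @export
print.variant_params <- function(x, ...) {
  cat(sprintf(
    "<variant_params> %s: V0.5act %.2f mV, V0.5inact %.2f mV, floor %.4f, tau_rec %.2f ms\n",
    x$name, x$v_half_act_mV, x$v_half_inact_mV, x$persistent_frac, x$tau_rec_ms
  ))
  invisible(x)
}

#' Coerce to variant parameters
#'
#' Accepts a `variant_params` object, a one-row data frame with the variant
#' table columns, or a named list.
#'
#' @param x Object to coerce.
#' @return A `variant_params` object.
#' @export
as_variant_params <- function(x) {
  if (inherits(x, "variant_params")) return(x)
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected exactly one variant row", call. = FALSE)
    x <- as.list(x)
  }
  if (!is.list(x) || !all(VARIANT_COLUMNS %in% names(x))) {
    stop("cannot interpret object as variant parameters", call. = FALSE)
  }
  do.call(variant_params, x[VARIANT_COLUMNS])
}

#' Load a variant parameter table
#'
#' Reads the comma-delimited parameter file (header
#' `name,peak_density_pA_per_pF,...,non_inactivating`), validates every row
#' against the `variant_params` invariants, and returns a tibble with one row
#' per variant. With `path = NULL` the packaged table of the twelve
#' characterized variants is loaded.
#'
#' @param path Path to a CSV file, or `NULL` for the packaged table.
#' @return A tibble of class `variant_library`.
#' @export
#' @examples
#' lib <- load_variant_table()
#' lib$name
load_variant_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nav12_variants.csv", package = "navclamp")
  }
  if (!file.exists(path)) stop("variant table not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no variants: the table '", path, "' is empty", call. = FALSE)
  extra <- setdiff(names(raw), VARIANT_COLUMNS)
  missing <- setdiff(VARIANT_COLUMNS, names(raw))
  if (length(extra)) {
    stop("unknown column(s) in variant table: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  if (length(missing)) {
    stop("missing column(s) in variant table: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- setdiff(VARIANT_COLUMNS, c("name", "non_inactivating"))
  for (cn in num_cols) {
    if (!is.numeric(raw[[cn]]) || anyNA(raw[[cn]])) {
      stop("column '", cn, "' must be numeric with no missing values", call. = FALSE)
    }
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicate variant name(s): ",
         paste(unique(raw$name[duplicated(raw$name)]), collapse = ", "),
         call. = FALSE)
  }
  raw$non_inactivating <- as.logical(raw$non_inactivating)
  for (i in seq_len(nrow(raw))) {
    p <- as.list(raw[i, , drop = FALSE])
    validate_variant_params(p)
  }
  structure(as_tibble(raw[VARIANT_COLUMNS]),
            class = c("variant_library", class(tibble())))
}

#' Write a variant table to CSV
#'
#' Round-trips with [load_variant_table()].
#'
#' @param library A `variant_library` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(library, path) {
  stopifnot(is.data.frame(library), all(VARIANT_COLUMNS %in% names(library)))
  utils::write.csv(library[VARIANT_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Look up one variant from a library
#'
#' @param name Variant label, e.g. `"N1662D"`.
#' @param library A `variant_library`; defaults to the packaged table.
#' @return A `variant_params` object.
#' @export
nav_variant <- function(name, library = load_variant_table()) {
  i <- match(name, library$name)
  if (is.na(i)) {
    stop("unknown variant '", name, "'; available: ",
         paste(library$name, collapse = ", "), call. = FALSE)
  }
  as_variant_params(library[i, ])
}

#' Table of per-variant measurement dispersion
#'
#' Standard errors of the mean and experiment counts for the five measured
#' quantities, used by the synthetic-cell sampler to reconstruct population
#' standard deviations (SD = SEM * sqrt(n)).
#'
#' @return A tibble with one row per variant.
#' @export
load_variability_table <- function() {
  path <- system.file("extdata", "nav12_variability.csv", package = "navclamp")
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
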