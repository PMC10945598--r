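#' Read a long-format titration table
#'
#' Expected columns: `variant`, `temperature_K`, `replicate`,
#' `protein_total_uM`, `ligand_total_uM`, `n_bound` and either
#' `mole_fraction` or `intensity` (one row per species per titration point).
#' Intensities are converted to mole fractions by per-point normalisation;
#' mole fractions are renormalised within each (variant, temperature,
#' replicate, ligand_total) group so every species vector sums to 1.
#'
#' @param path Path to a CSV file.
#' @return A validated titration tibble with a `mole_fraction` column.
#' @export
read_titration_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  validate_titration(raw, require_meta = TRUE)
}

#' Validate and renormalise a titration table
#'
#' @param data Data frame in the [read_titration_csv()] schema (the metadata
#'   columns may be absent when `require_meta = FALSE`).
#' @param require_meta Require `variant`, `temperature_K`, `replicate`.
#' @return A tibble with renormalised `mole_fraction`.
#' @export
validate_titration <- function(data, require_meta = TRUE) {
  data <- tibble::as_tibble(data)
  needed <- c("ligand_total_uM", "n_bound")
  if (require_meta) {
    needed <- c("variant", "temperature_K", "replicate",
                "protein_total_uM", needed)
  }
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    stop("titration table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"mole_fraction" %in% names(data)) {
    if (!"intensity" %in% names(data)) {
      stop("titration table needs a `mole_fraction` or `intensity` column",
           call. = FALSE)
    }
    if (any(data$intensity < 0)) {
      stop("intensities must be non-negative", call. = FALSE)
    }
    data$mole_fraction <- data$intensity
  }
  if (any(data$ligand_total_uM < 0)) {
    stop("`ligand_total_uM` must be non-negative", call. = FALSE)
  }
  if (any(data$mole_fraction < -1e-9)) {
    stop("mole fractions must be non-negative", call. = FALSE)
  }
  keys <- intersect(c("variant", "temperature_K", "replicate",
                      "ligand_total_uM"), names(data))
  data <- dplyr::ungroup(dplyr::mutate(
    dplyr::group_by(data, dplyr::across(dplyr::all_of(keys))),
    mole_fraction = {
      f <- pmax(.data$mole_fraction, 0)
      if (sum(f) <= 0) {
        stop("titration point with all-zero species abundances", call. = FALSE)
      }
      f / sum(f)
    }
  ))
  data
}

#' Read a dissociation-constant table
#'
#' Reads a K_D summary table in the published layout: `variant`,
#' `temperature_K`, optional `replicate`, and `KD1_uM`, `KD2_uM`, `KD3_uM`
#' columns (blank cells allowed for variants with fewer resolvable binding
#' events). Returns the table in long form, one row per binding event.
#'
#' @param path Path to a CSV file.
#' @return A tibble with `variant`, `temperature_K`, (`replicate`,) `event`,
#'   `kd_uM` and, when `KD<n>_sd` columns are present, `kd_sd`.
#' @export
read_kd_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  kd_table_to_long(raw)
}

#' @rdname read_kd_csv
#' @param data A wide K_D data frame already in memory.
#' @export
kd_table_to_long <- function(data) {
  data <- tibble::as_tibble(data)
  kd_cols <- grep("^KD[123]_uM$", names(data), value = TRUE)
  if (!length(kd_cols)) {
    stop("no `KD<n>_uM` columns found", call. = FALSE)
  }
  ids <- intersect(c("variant", "temperature_K", "replicate"), names(data))
  long <- tidyr::pivot_longer(
    data, cols = dplyr::matches("^KD[123]_(uM|sd)$"),
    names_pattern = "KD([123])_(uM|sd)", names_to = c("event", ".value")
  )
  long <- dplyr::filter(long, !is.na(.data$uM))
  long$event <- as.integer(long$event)
  out <- dplyr::rename(long, kd_uM = "uM")
  if ("sd" %in% names(out)) out <- dplyr::rename(out, kd_sd = "sd")
  dplyr::arrange(out[, c(ids, "event", setdiff(names(out), c(ids, "event")))],
                 .data$variant, .data$event, .data$temperature_K)
}
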