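#' Bliss-independence additive expectation
#'
#' For two independently acting inhibitors with inhibition fractions `ir1`
#' and `ir2`, the expected combined inhibition is
#' `ir1 + ir2 - ir1 * ir2`. Vectorized.
#'
#' @param ir1,ir2 Inhibition rates as fractions in \[0, 1\].
#' @return The Bliss additive inhibition rate(s).
#' @examples
#' bliss_additive(0.5, 0.5) # 0.75
#' @export
bliss_additive <- function(ir1, ir2) {
  if (any(!is.finite(ir1)) || any(!is.finite(ir2)) ||
    any(ir1 < 0 | ir1 > 1) || any(ir2 < 0 | ir2 > 1)) {
    abort("Inhibition rates must be fractions in [0, 1].")
  }
  ir1 + ir2 - ir1 * ir2
}

# Percentage inputs (any value > 1) are converted to fractions with a
# warning; the wet-lab literature reports both conventions.
as_inhibition_fraction <- function(x) {
  x <- as.numeric(x)
  if (any(x > 1, na.rm = TRUE)) {
    warn("Inhibition rates > 1 detected; interpreting as percentages and dividing by 100.")
    x <- x / 100
  }
  x
}

# Joint conversion so a percentage-scale table triggers one warning and the
# three rate columns stay on a common scale.
ir_columns <- function(table) {
  cols <- c("ir1", "ir2", "ir_combo")
  missing_cols <- setdiff(cols, names(table))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "Dose-response table lacks column(s): %s",
      paste(missing_cols, collapse = ", ")
    ))
  }
  vals <- lapply(table[cols], as.numeric)
  if (any(unlist(vals) > 1, na.rm = TRUE)) {
    warn("Inhibition rates > 1 detected; interpreting as percentages and dividing by 100.")
    vals <- lapply(vals, function(x) x / 100)
  }
  vals
}

#' Maximum increased inhibition rate (MIIR)
#'
#' The experimental synergy readout for a fixed-ratio dose series:
#' `MIIR = max(IR_syn - IR_add)` over doses, where `IR_syn` is the observed
#' combination inhibition and `IR_add` the Bliss additive expectation from
#' the single-agent rates at the same dose. Negative values indicate
#' sub-additive (possibly antagonistic) interaction. With
#' `effective_only = TRUE` the maximum is restricted to effective doses,
#' i.e. rows with combination inhibition strictly above `threshold`.
#'
#' @param table Dose-response tibble with columns `ir1`, `ir2`, `ir_combo`
#'   (see [read_dose_response()] / [simulate_dose_response()]). Percentage
#'   inputs are auto-converted.
#' @param effective_only Restrict to rows passing [effective_combinations()].
#' @param threshold Effectiveness cutoff on the combination inhibition.
#' @return A one-row tibble: `miir`, `dose_index` (row attaining the
#'   maximum), `n_doses`, `effective_only`.
#' @export
miir <- function(table, effective_only = FALSE, threshold = 0.70) {
  if (nrow(table) == 0) {
    abort("Dose-response table is empty.")
  }
  irs <- ir_columns(table)
  ir_combo <- irs$ir_combo
  delta <- ir_combo - bliss_additive(irs$ir1, irs$ir2)
  rows <- seq_len(nrow(table))
  if (effective_only) {
    rows <- rows[ir_combo > threshold]
    if (length(rows) == 0) {
      warn(sprintf("No dose reaches a combination inhibition above %g; MIIR is NA.", threshold))
      return(tibble(
        miir = NA_real_, dose_index = NA_integer_,
        n_doses = nrow(table), effective_only = TRUE
      ))
    }
  }
  best <- rows[which.max(delta[rows])]
  tibble(
    miir = delta[best], dose_index = best,
    n_doses = nrow(table), effective_only = effective_only
  )
}

#' Flag effective combination doses
#'
#' A dose is effective when the observed combination inhibition rate is
#' strictly greater than the threshold (default 70%).
#'
#' @param table Dose-response tibble.
#' @param threshold Cutoff in (0, 1).
#' @return `table` with a logical `effective` column appended.
#' @export
effective_combinations <- function(table, threshold = 0.70) {
  if (threshold <= 0 || threshold >= 1) {
    abort("`threshold` must lie in (0, 1).")
  }
  table$effective <- as_inhibition_fraction(table$ir_combo) > threshold
  table
}

#' Dose-response curves with the Bliss expectation
#'
#' @param table Dose-response tibble.
#' @return A ggplot comparing observed combination inhibition with the
#'   Bliss additive expectation across the dose series.
#' @export
plot_dose_response <- function(table) {
  df <- tibble(
    dose_index = seq_len(nrow(table)),
    observed = as_inhibition_fraction(table$ir_combo),
    bliss = bliss_additive(
      as_inhibition_fraction(table$ir1),
      as_inhibition_fraction(table$ir2)
    )
  )
  df <- tidyr::pivot_longer(df, c("observed", "bliss"),
    names_to = "curve", values_to = "inhibition"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$dose_index, y = .data$inhibition, colour = .data$curve
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(observed = "#d7191c", bliss = "#2c7fb8")) +
    ggplot2::labs(
      x = "dose index", y = "inhibition rate", colour = NULL,
      title = "Observed combination vs. Bliss additive expectation"
    ) +
    ggplot2::theme_minimal()
}
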