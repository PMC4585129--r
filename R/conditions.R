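#' Default experimental conditions of the incubation study
#'
#' Returns the seven-condition study design: four methane-oxidizing
#' conditions crossing low/high sulfate with low/high sulfide, and three
#' controls (sulfate only, methane only, sulfide only). Concentrations are
#' the time-averaged dissolved concentrations of each condition; dissolved
#' methane is fixed at its saturation value of 1.31 mM (salinity 30, 20 degC)
#' wherever methane was supplied in the headspace.
#'
#' @return A data.frame with columns `id`, `sulfate_mM`, `sulfide_mM`,
#'   `methane_mM`, `co2_mM`, `methane_added`.
#' @seealso [energetics_table()], [generate_study()]
#' @export
#' @examples
#' incubation_conditions()
incubation_conditions <- function() {
  data.frame(
    id = c("1: CH4 highSO4", "2: CH4 highSO4 highS", "3: CH4 lowSO4",
           "4: CH4 lowSO4 highS", "5: highSO4", "6: CH4", "7: highS"),
    sulfate_mM = c(21.6, 21.1, 3.6, 4.0, 21.6, 0.1, 0.4),
    sulfide_mM = c(0.4, 3.8, 0.4, 3.6, 0.2, 0.1, 3.0),
    methane_mM = c(1.31, 1.31, 1.31, 1.31, NA, 1.31, NA),
    co2_mM = c(3.8, 6.9, 4.4, 6.4, 3.2, 2.7, 4.4),
    methane_added = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Construct a single incubation condition record
#'
#' @param id Short label for the condition.
#' @param sulfate_mM,sulfide_mM,methane_mM,co2_mM Dissolved concentrations in
#'   mM. Total dissolved sulfide is treated as HS- (medium pH 7.2-7.5).
#' @param methane_added Logical; whether methane was supplied in the
#'   headspace.
#' @return A one-row data.frame in the same layout as
#'   [incubation_conditions()].
#' @export
incubation_condition <- function(id, sulfate_mM, sulfide_mM, methane_mM,
                                 co2_mM, methane_added = TRUE) {
  stopifnot(is.character(id), length(id) == 1L)
  conc <- c(sulfate_mM, sulfide_mM, co2_mM)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  if (!is.na(methane_mM) && methane_mM < 0)
    stop("methane_mM must be >= 0", call. = FALSE)
  data.frame(id = id, sulfate_mM = sulfate_mM, sulfide_mM = sulfide_mM,
             methane_mM = methane_mM, co2_mM = co2_mM,
             methane_added = isTRUE(methane_added),
             stringsAsFactors = FALSE)
}

#' Read or write a condition table
#'
#' Condition tables are plain CSV with header
#' `id,sulfate_mM,sulfide_mM,methane_mM,co2_mM,methane_added`.
#'
#' @param file Path to a CSV file.
#' @return `read_conditions()` returns the condition data.frame.
#' @export
read_conditions <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("id", "sulfate_mM", "sulfide_mM", "methane_mM", "co2_mM",
            "methane_added")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("condition file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  x$methane_added <- as.logical(x$methane_added)
  x[need]
}

#' @rdname read_conditions
#' @param conditions A condition data.frame.
#' @export
write_conditions <- function(conditions, file) {
  utils::write.csv(conditions, file, row.names = FALSE)
  invisible(file)
}
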