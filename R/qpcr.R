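# qPCR cycle-threshold (CT) quantification of the 20-gene panel in the
# second cell line, converted to per-chemical dose LFC profiles with the
# same schema as the RNA-seq LFC panel so the network stage consumes
# either source.

#' Reference-normalised CT differences
#'
#' `dCT = CT_gene - CT_reference` per (chemical, dose level, timepoint,
#' replicate) sample, with GAPDH as the default internal control.
#'
#' @param ct_table Long CT table ([read_ct_table()] format).
#' @param reference_gene Internal-control gene (default `"GAPDH"`).
#' @return The table without the reference rows, with a `dct` column.
#' @export
delta_ct <- function(ct_table, reference_gene = "GAPDH") {
  keys <- c("chemical", "dose_level", "timepoint", "replicate")
  ref <- dplyr::filter(ct_table, .data$gene == reference_gene)
  if (nrow(ref) == 0) {
    abort(paste0("Reference gene '", reference_gene, "' not in table."))
  }
  ref <- select(ref, all_of(keys), ref_ct = "ct")
  out <- ct_table %>%
    dplyr::filter(.data$gene != reference_gene) %>%
    left_join(ref, by = keys)
  if (any(is.na(out$ref_ct))) {
    miss <- distinct(out[is.na(out$ref_ct), keys])
    abort(paste0("Sample(s) without a reference-gene measurement: ",
                 paste(do.call(paste, c(head(miss, 3), sep = "/")),
                       collapse = ", ")))
  }
  out$dct <- out$ct - out$ref_ct
  select(out, -"ref_ct")
}

#' ddCT log fold changes vs vehicle
#'
#' Per (chemical, dose level, timepoint, gene), dCT is averaged over the
#' replicates; the matched solvent vehicle's dCT (averaged over all its
#' replicates at the same timepoint) is subtracted:
#' `ddCT = dCT_dose - dCT_vehicle`. The result is stored as the LFC panel
#' entry `lfc_sign * ddCT`. The default `lfc_sign = +1` records ddCT
#' itself as the log fold change; `lfc_sign = -1` gives the expression
#' fold-change orientation (a lower CT means more transcript). A
#' classifier consuming both domains is insensitive to a consistent
#' global sign flip.
#'
#' @param dct Output of [delta_ct()].
#' @param sheet Sample sheet mapping each chemical to its solvent
#'   (vehicle rows in the CT table carry the solvent name as `chemical`).
#' @param lfc_sign `+1` (default) or `-1`.
#' @return LFC panel tibble (`chemical`, `dose_level`, `timepoint` + one
#'   column per gene), exposed conditions only.
#' @export
ddct_lfc <- function(dct, sheet, lfc_sign = 1) {
  stopifnot(lfc_sign %in% c(-1, 1))
  sheet <- validate_sample_sheet(sheet)
  solvent_of <- distinct(
    dplyr::filter(sheet, .data$dose_level != "vehicle"),
    .data$chemical, .data$solvent)
  veh <- dct %>%
    dplyr::filter(.data$dose_level == "vehicle") %>%
    group_by(solvent = .data$chemical, .data$timepoint, .data$gene) %>%
    summarise(veh_dct = mean(.data$dct), .groups = "drop")
  if (nrow(veh) == 0) abort("No vehicle rows in the CT table.")
  out <- dct %>%
    dplyr::filter(.data$dose_level != "vehicle") %>%
    group_by(.data$chemical, .data$dose_level, .data$timepoint,
             .data$gene) %>%
    summarise(dct = mean(.data$dct), .groups = "drop") %>%
    left_join(solvent_of, by = "chemical") %>%
    left_join(veh, by = c("solvent", "timepoint", "gene"))
  if (any(is.na(out$veh_dct))) {
    abort("Missing matched vehicle dCT for some condition/gene.")
  }
  out$lfc <- lfc_sign * (out$dct - out$veh_dct)
  wide <- tidyr::pivot_wider(
    select(out, "chemical", "dose_level", "timepoint", "gene", "lfc"),
    names_from = "gene", values_from = "lfc")
  arrange(wide, .data$chemical, .data$timepoint, .data$dose_level)
}
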