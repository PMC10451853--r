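#' Bat class taxonomy
#'
#' The label set used throughout the package: three Pipistrellus species
#' (`P_pip`, `P_nat`, `P_pyg`), *Nyctalus noctula* (`N_noc`),
#' *Barbastella barbastellus* (`B_bar`), the genus-level classes `Myotis` and
#' `Plecotus`, the group `Nyctaloid` (several species with near-identical
#' calls, *N. noctula* among them), the hybrid classes `P_low` and `P_high`
#' (calls in the frequency band shared by two Pipistrellus species that cannot
#' be attributed to one of them), and `noise`.
#'
#' Each bat label carries the band in which its frequency of maximum energy
#' (peak frequency) is expected to fall, in kHz. These bands drive the
#' synthetic pulse generator and are the diagnostic feature the classifiers
#' exploit.
#'
#' @return A data.frame with columns `label`, `genus` (genus-level class or
#'   `"excluded"`), `peak_lo_khz`, `peak_hi_khz` (NA for `B_bar` and `noise`).
#' @export
#' @examples
#' bat_taxonomy()
bat_taxonomy <- function() {
  data.frame(
    label = c("P_pip", "P_nat", "P_pyg", "N_noc", "B_bar",
              "Myotis", "Plecotus", "Nyctaloid", "P_low", "P_high", "noise"),
    genus = c("Pipistrellus", "Pipistrellus", "Pipistrellus", "Nyctaloid",
              "excluded", "Myotis", "Plecotus", "Nyctaloid",
              "Pipistrellus", "Pipistrellus", "excluded"),
    peak_lo_khz = c(42, 35, 52, 12, NA, 25, 22, 14, 40, 50, NA),
    peak_hi_khz = c(50, 40, 60, 20, NA, 45, 35, 28, 42, 52, NA),
    stringsAsFactors = FALSE
  )
}

#' Map a class label to its genus-level class
#'
#' All Pipistrellus species labels (including the hybrid classes `P_low` and
#' `P_high`) map to `Pipistrellus`; `N_noc` folds into `Nyctaloid`; `Myotis`,
#' `Plecotus` and `Nyctaloid` map to themselves. `B_bar` and `noise` are
#' excluded from genus-level experiments and map to `"excluded"`. The mapping
#' is idempotent on genus labels.
#'
#' @param label character vector of taxonomy labels.
#' @return character vector of genus-level labels (or `"excluded"`).
#' @export
#' @examples
#' map_to_genus(c("P_nat", "N_noc", "noise"))
map_to_genus <- function(label) {
  tax <- bat_taxonomy()
  bad <- setdiff(label, c(tax$label, genus_labels()))
  if (length(bad) > 0)
    stop("unknown taxonomy label(s): ", paste(bad, collapse = ", "))
  out <- tax$genus[match(label, tax$label)]
  # idempotent on genus-level labels (Pipistrellus has no species row)
  out[is.na(out)] <- label[is.na(out)]
  out
}

#' Peak-frequency band of a bat class
#'
#' @param label a single taxonomy label.
#' @return numeric c(lo, hi) in kHz.
#' @export
peak_band <- function(label) {
  tax <- bat_taxonomy()
  i <- match(label, tax$label)
  if (is.na(i)) stop("unknown taxonomy label: ", label)
  band <- c(tax$peak_lo_khz[i], tax$peak_hi_khz[i])
  if (anyNA(band)) stop("class ", label, " has no peak-frequency band")
  band
}

#' Genus-level class labels used in genus experiments
#' @return character vector of the four genus classes.
#' @export
genus_labels <- function() c("Nyctaloid", "Myotis", "Plecotus", "Pipistrellus")
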