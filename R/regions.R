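#' Cortical region labels
#'
#' The 39 cortical region labels used per hemisphere, following the automated
#' anatomical labeling (AAL) abbreviation convention for the 78 cortical
#' regions (39 homologous left/right pairs; subcortical and cerebellar
#' structures excluded). These are the anatomical parents of the 512
#' upsampled subregions and the level at which local graph metrics are
#' aggregated and lateralized.
#'
#' @return character vector of 39 region abbreviations.
#' @export
#' @examples
#' length(aal_cortical_regions())
aal_cortical_regions <- function() {
  c(
    "PreCG", "SFGdor", "ORBsup", "MFG", "ORBmid", "IFGoperc", "IFGtriang",
    "ORBinf", "ROL", "SMA", "OLF", "SFGmed", "ORBsupmed", "REC", "INS",
    "ACG", "MCG", "PCG", "PHG", "CAL", "CUN", "LING", "SOG", "MOG", "IOG",
    "FFG", "PCUN", "PoCG", "SPG", "IPL", "SMG", "ANG", "PCL", "HES", "STG",
    "TPOsup", "MTG", "TPOmid", "ITG"
  )
}

# Region labels for a possibly reduced-scale surface: the first n canonical
# labels, or synthetic labels past 39 (test-scale configs only).
region_labels <- function(n) {
  base <- aal_cortical_regions()
  if (n <= length(base)) {
    base[seq_len(n)]
  } else {
    c(base, sprintf("SYN%02d", seq_len(n - length(base))))
  }
}

#' Homologous region pairs of a parcellation
#'
#' Left/right homologues are matched by shared anatomical label; the pairing
#' is the bijection between the two hemispheres' region lists that underlies
#' every local asymmetry index.
#'
#' @param subregions subregion table with columns `region` and `hemisphere`.
#' @return tibble with one row per region present in both hemispheres.
#' @export
homologous_pairs <- function(subregions) {
  lt <- unique(subregions$region[subregions$hemisphere == "L"])
  rt <- unique(subregions$region[subregions$hemisphere == "R"])
  if (!setequal(lt, rt)) {
    stop_input("left and right hemisphere region lists differ; homologous pairing undefined")
  }
  tibble(region = sort(lt))
}
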