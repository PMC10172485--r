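#' Canonical 21-electrode 10-20 montage
#'
#' Electrode labels of the 21 canonical sites of the international 10-20
#' system, in the fixed order used throughout the package for adjacency
#' matrices and serialized recordings. Restricting network analysis to these
#' sites is the conventional way to limit volume-conduction effects when
#' scalp electrodes serve as network nodes.
#'
#' @return Character vector of 21 electrode labels.
#' @export
#' @examples
#' canonical_montage()
canonical_montage <- function() {
  c("FP1", "FP2", "FPz", "F7", "F3", "F4", "Fz", "F8",
    "T7", "C3", "C4", "Cz", "T8",
    "P7", "P3", "P4", "Pz", "P8",
    "O1", "O2", "Oz")
}

#' Default medial fronto-parietal edge set
#'
#' All unordered pairs among the medial fronto-parietal electrodes
#' FPz, Fz, Cz, Pz, P3, P4 -- a scalp-level proxy for default-mode-network
#' connectivity. Used as the default location of the planted coherence
#' effect in the synthetic cohort.
#'
#' @return Two-column character matrix, one row per electrode pair.
#' @export
default_dmn_edges <- function() {
  nodes <- c("FPz", "Fz", "Cz", "Pz", "P3", "P4")
  t(utils::combn(nodes, 2))
}

# Relative blink amplitude per electrode row: ocular artifacts are largest
# at the frontal pole and decay toward posterior sites.
blink_topography <- function(labels) {
  w <- c(FP1 = 1, FP2 = 1, FPz = 1,
         F7 = 0.45, F3 = 0.45, F4 = 0.45, Fz = 0.45, F8 = 0.45,
         T7 = 0.18, C3 = 0.18, C4 = 0.18, Cz = 0.18, T8 = 0.18,
         P7 = 0.07, P3 = 0.07, P4 = 0.07, Pz = 0.07, P8 = 0.07,
         O1 = 0.03, O2 = 0.03, Oz = 0.03)
  out <- w[labels]
  out[is.na(out)] <- 0.1
  unname(out)
}
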