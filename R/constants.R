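# Physico-chemical reference tables used by the structural features.

# van der Waals radii (Angstrom) by element, for Shrake-Rupley SASA.
ATOM_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Pseudo-atom radius used when a model carries only CA atoms.
CA_ONLY_RADIUS <- 2.0

# Theoretical maximum accessible surface area per residue (Angstrom^2),
# Tien et al. 2013 "theoretical" column; used for relative accessibility.
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167,
             E = 223, Q = 225, G = 104, H = 224, I = 197,
             L = 201, K = 236, M = 224, F = 240, P = 159,
             S = 155, T = 172, W = 285, Y = 263, V = 174,
             X = 197)

# Average residue masses (Da; amino-acid residues in a chain, i.e. minus
# water), for the exposed-mass feature.
RESIDUE_MASS <- c(A = 71.08, R = 156.19, N = 114.10, D = 115.09, C = 103.14,
                  E = 129.12, Q = 128.13, G = 57.05, H = 137.14, I = 113.16,
                  L = 113.16, K = 128.17, M = 131.19, F = 147.18, P = 97.12,
                  S = 87.08, T = 101.10, W = 186.21, Y = 163.18, V = 99.13,
                  X = 110.0)

# Hydrophobic (nonpolar) residues for the surface score.
NONPOLAR_AA <- c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C")

# Relative-accessibility threshold above which a residue counts as exposed.
EXPOSED_THRESHOLD <- 0.25

# External score columns recognised in score tables, with how each enters
# the feature vector: "formula" scores use the published length-normalised
# linear maps; "linear" scores use configurable -P/(c*L) maps; "passthrough"
# scores are already in [0,1].
EXTERNAL_SCORE_KINDS <- c(dfire2 = "formula", rwplus = "formula",
                          rf_cb_srs_od = "formula",
                          dope = "linear", goap = "linear", opus = "linear",
                          proq2 = "passthrough", modelevaluator = "passthrough",
                          qprob = "passthrough")

# Default divisor constants for the linear -P/(c*L) maps (calibration
# knobs; the published formulas only cover dfire2/rwplus/rf_cb_srs_od).
LINEAR_SCALE_DEFAULTS <- c(dope = 2.0, goap = 20.0, opus = 2.0)

# Canonical feature orders.
FEATURE_KEYS_FULL16 <- c("SU", "EM", "ES", "SA", "RF_CB_SRS_OD", "DFIRE2",
                         "DOPE", "GOAP", "OPUS", "PROQ2", "RWPLUS",
                         "MODELEVALUATOR", "SS", "SP", "EC", "QPROB")
FEATURE_KEYS_DEEPQA9 <- c("SU", "DOPE", "GOAP", "OPUS", "RWPLUS",
                          "MODELEVALUATOR", "SP", "EC", "QPROB")

# Map external column name -> feature key.
EXTERNAL_TO_KEY <- c(dfire2 = "DFIRE2", rwplus = "RWPLUS",
                     rf_cb_srs_od = "RF_CB_SRS_OD", dope = "DOPE",
                     goap = "GOAP", opus = "OPUS", proq2 = "PROQ2",
                     modelevaluator = "MODELEVALUATOR", qprob = "QPROB")

# Feature keys computed from the structure itself.
COMPUTED_KEYS <- c("SU", "EM", "ES", "SA", "SS", "SP", "EC")

#' Feature-set key order
#'
#' @param name "full16" (all 16 features, Table order: surface, exposed
#'   mass, exposed surface, solvent-accessibility agreement, five energy
#'   scores, three QA scores, secondary-structure scores, compactness,
#'   Qprob) or "deepqa9" (the reduced 9-feature set).
#' @return character vector of ordered feature keys.
#' @export
featureSetKeys <- function(name = c("full16", "deepqa9")) {
  name <- match.arg(name)
  if (name == "full16") FEATURE_KEYS_FULL16 else FEATURE_KEYS_DEEPQA9
}
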