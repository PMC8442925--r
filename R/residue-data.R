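#' @keywords internal
"_PACKAGE"

## Canonical one-letter alphabet used throughout.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

## Kyte-Doolittle hydropathy index.
KD_HYDROPATHY <- c(I = 4.5, V = 4.2, L = 3.8, F = 2.8, C = 2.5, M = 1.9,
                   A = 1.8, G = -0.4, T = -0.7, S = -0.8, W = -0.9,
                   Y = -1.3, P = -1.6, H = -3.2, E = -3.5, Q = -3.5,
                   D = -3.5, N = -3.5, K = -3.9, R = -4.5)

## Chou-Fasman beta-sheet conformational propensities.
BETA_PROPENSITY <- c(V = 1.70, I = 1.60, Y = 1.47, F = 1.38, W = 1.37,
                     L = 1.30, C = 1.19, T = 1.19, Q = 1.10, M = 1.05,
                     R = 0.93, N = 0.89, H = 0.87, A = 0.83, S = 0.75,
                     G = 0.75, K = 0.74, P = 0.55, D = 0.54, E = 0.37)

## Formal side-chain charge at neutral pH (His treated as neutral).
RESIDUE_CHARGE <- c(A = 0, R = 1, N = 0, D = -1, C = 0, Q = 0, E = -1,
                    G = 0, H = 0, I = 0, L = 0, K = 1, M = 0, F = 0,
                    P = 0, S = 0, T = 0, W = 0, Y = 0, V = 0)

## Approximate canonical Calpha -> side-chain-centroid distances (Angstrom),
## used to place centroid pseudo-atoms along the sheet normal.
SIDECHAIN_EXTENT <- c(A = 1.5, R = 4.1, N = 2.5, D = 2.5, C = 2.1,
                      Q = 3.0, E = 3.1, G = 0.0, H = 3.2, I = 2.3,
                      L = 2.6, K = 3.5, M = 2.9, F = 3.4, P = 1.9,
                      S = 1.9, T = 1.9, W = 3.9, Y = 3.8, V = 2.0)

## Polarity class used by the variable-dielectric electrostatics:
## charged residues are classed by charge; these are the polar
## (hydrogen-bond capable) side chains among the neutrals.
POLAR_NEUTRAL <- c("S", "T", "N", "Q", "Y", "H", "W")

#' Polarity class of a residue (nonpolar, polar, charged)
#'
#' Used to look up the effective pairwise dielectric constant in the
#' electrostatic term of the binding-energy model.
#'
#' @param code character vector of one-letter residue codes.
#' @return character vector in \code{c("nonpolar", "polar", "charged")}.
#' @export
residue_polarity_class <- function(code) {
  stopifnot(all(code %in% AA20))
  out <- rep("nonpolar", length(code))
  out[code %in% POLAR_NEUTRAL] <- "polar"
  out[RESIDUE_CHARGE[code] != 0] <- "charged"
  out
}

#' Packaged expected-contacts amyloidogenicity scale
#'
#' Per-residue expected number of residue-residue contacts at an 8 Angstrom
#' radius, the scale underlying contact-based amyloidogenicity prediction.
#' The packaged values are an approximate reconstruction of the published
#' scale (shipped as a documented CSV under \code{extdata}); the screening
#' logic itself is independent of the resource and is tested against
#' synthetic scales.
#'
#' @param path optional path to a CSV with columns \code{residue,value}
#'   overriding the packaged resource.
#' @return named numeric vector over the 20 standard residues.
#' @export
expected_contacts_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "expected_contacts_scale.csv",
                        package = "coapep", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, comment.char = "#",
                         stringsAsFactors = FALSE)
  if (!all(c("residue", "value") %in% names(tab))) {
    stop("scale CSV must have columns 'residue' and 'value'")
  }
  sc <- stats::setNames(as.numeric(tab$value), tab$residue)
  missing <- setdiff(AA20, names(sc))
  if (length(missing)) {
    stop("scale is missing residues: ", paste(missing, collapse = ", "))
  }
  sc[AA20]
}
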