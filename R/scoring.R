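## Design score: gamma = dG_binding + lambda * P_agg, lower is better.
##
## dG_binding is a per-peptide interaction energy of the pair threaded onto
## the fixed fibril scaffold: backbone hydrogen bonds from the scaffold
## registry, side-chain contact energies within a distance cutoff, Coulomb
## electrostatics with a pairwise variable internal dielectric, and a
## desolvation penalty per charged residue buried at the sheet-sheet
## interface.  P_agg is a sequence-intrinsic self-aggregation propensity
## from a weighted hydropathy / beta-propensity / charge profile.

#' Default side-chain contact energy table
#'
#' A 20x20 symmetric table (kcal/mol) generated from a documented mixing
#' rule: a favorable hydrophobic product term
#' \code{-w_hp * max(kd_i, 0) * max(kd_j, 0)} plus a hydrogen-bonding bonus
#' for pairs of polar side chains. Any knowledge-based table with the same
#' layout can be supplied instead (see \code{\link{read_contact_table}}).
#'
#' @param w_hp weight of the hydrophobic product term.
#' @param polar_bonus energy (kcal/mol) for a polar-polar side-chain pair.
#' @return 20x20 symmetric numeric matrix with residue dimnames.
#' @export
default_contact_table <- function(w_hp = 0.12, polar_bonus = -0.5) {
  p <- pmax(KD_HYDROPATHY[AA20], 0)
  hb <- AA20 %in% c(POLAR_NEUTRAL, "K", "R", "D", "E", "S")
  m <- -w_hp * outer(p, p) + polar_bonus * outer(hb, hb)
  dimnames(m) <- list(AA20, AA20)
  m
}

#' Read a contact table from CSV
#'
#' Expects a 20x20 numeric table with residue one-letter codes as the
#' first column and as column headers.
#'
#' @param path CSV file path.
#' @return 20x20 symmetric matrix.
#' @export
read_contact_table <- function(path) {
  tab <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(tab)
  if (!all(AA20 %in% rownames(m)) || !all(AA20 %in% colnames(m))) {
    stop("contact table must cover all 20 standard residues")
  }
  m <- m[AA20, AA20]
  if (max(abs(m - t(m))) > 1e-9) stop("contact table must be symmetric")
  m
}

#' Energy model parameters
#'
#' @param hbond_energy energy per backbone hydrogen bond (kcal/mol).
#' @param contact_table 20x20 symmetric side-chain contact energies
#'   (kcal/mol).
#' @param dielectric_by_class named relative permittivities for the
#'   \code{nonpolar}, \code{polar} and \code{charged} residue classes; the
#'   pairwise effective dielectric is the maximum of the two classes.
#' @param coulomb_constant 332.06 kcal A / (mol e^2).
#' @param contact_cutoff side-chain centroid distance cutoff for the
#'   contact term (Angstrom).
#' @param desolvation_penalty energy per buried charged residue (kcal/mol).
#' @param burial_margin margin (Angstrom) shrinking the inter-sheet slab
#'   used by the burial rule.
#' @param sidechain_extent per-residue Calpha-to-centroid distances.
#' @return object of class \code{energy_params}.
#' @export
energy_params <- function(hbond_energy = -1.5,
                          contact_table = default_contact_table(),
                          dielectric_by_class = c(nonpolar = 1, polar = 2,
                                                  charged = 4),
                          coulomb_constant = 332.06,
                          contact_cutoff = 6.5,
                          desolvation_penalty = 1.0,
                          burial_margin = 0.0,
                          sidechain_extent = SIDECHAIN_EXTENT) {
  stopifnot(contact_cutoff > 0, all(dielectric_by_class >= 1),
            all(c("nonpolar", "polar", "charged") %in%
                  names(dielectric_by_class)))
  if (max(abs(contact_table - t(contact_table))) > 1e-9) {
    stop("contact_table must be symmetric")
  }
  structure(list(hbond_energy = hbond_energy, contact_table = contact_table,
                 dielectric_by_class = dielectric_by_class,
                 coulomb_constant = coulomb_constant,
                 contact_cutoff = contact_cutoff,
                 desolvation_penalty = desolvation_penalty,
                 burial_margin = burial_margin,
                 sidechain_extent = sidechain_extent),
            class = "energy_params")
}

#' Combine binding energy and aggregation propensity into the design score
#'
#' \code{gamma = dg + lambda * p_agg}; lower scores mean stronger predicted
#' co-binding with weaker self-aggregation.
#'
#' @param dg per-peptide binding free energy (kcal/mol).
#' @param p_agg per-peptide aggregation propensity (dimensionless).
#' @param lambda_weight weighting factor (the published searches used 3.0
#'   and 4.0).
#' @return combined score (kcal/mol).
#' @examples
#' combine_score(-25.21, -0.18, 4.0)  # -25.93
#' @export
combine_score <- function(dg, p_agg, lambda_weight) {
  stopifnot(is.finite(dg), is.finite(p_agg), is.finite(lambda_weight))
  dg + lambda_weight * p_agg
}

## Burial test: project side-chain centroids onto the inter-sheet axis and
## flag charged residues strictly inside the slab between the two sheet
## mean planes (rotation/translation invariant).
buried_charged_count <- function(scaffold, res, cent, params) {
  sheets <- scaffold$slots$sheet
  if (length(unique(sheets)) < 2) return(0L)
  sheet_centroid <- function(s) {
    colMeans(do.call(rbind, scaffold$ca[sheets == s]))
  }
  us <- sort(unique(sheets))
  c1 <- sheet_centroid(us[1]); c2 <- sheet_centroid(us[2])
  axis <- c2 - c1
  axis <- axis / sqrt(sum(axis^2))
  lo <- sum(c1 * axis) + params$burial_margin
  hi <- sum(c2 * axis) - params$burial_margin
  n_buried <- 0L
  for (k in seq_along(cent)) {
    q <- RESIDUE_CHARGE[res[[k]]]
    proj <- cent[[k]] %*% axis
    n_buried <- n_buried + sum(q != 0 & proj > lo & proj < hi)
  }
  n_buried
}

#' Per-peptide binding energy of a pair on the scaffold
#'
#' Sums, over all inter-chain interactions: the backbone hydrogen-bond
#' term from the scaffold registry, side-chain contact energies within the
#' cutoff, Coulomb terms with the pairwise effective dielectric
#' \code{max(eps_i, eps_j)}, and the desolvation penalty for buried charged
#' residues; the total is divided by the number of peptides in the
#' scaffold. Deterministic and independent of slot enumeration order.
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @param scaffold a \code{\link{build_scaffold}} result with all slots
#'   assigned a species.
#' @param params an \code{\link{energy_params}} object.
#' @return list with \code{dg} (kcal/mol per peptide), \code{total}
#'   (kcal/mol) and \code{components} (hbond, contact, electrostatic,
#'   desolvation).
#' @export
binding_energy <- function(pair, scaffold, params = energy_params()) {
  if (any(!scaffold$slots$species %in% c("A", "B"))) {
    stop("scaffold has unassigned slot species")
  }
  res <- thread_sequences(scaffold, pair)
  cent <- sidechain_centroids(scaffold, pair, params$sidechain_extent)
  n_slots <- nrow(scaffold$slots)
  n_res <- scaffold$geometry$n_residues

  e_hbond <- params$hbond_energy * sum(scaffold$hbond_registry$n_hbonds)

  ## flatten centroids with chain labels
  all_cent <- do.call(rbind, cent)
  chain_of <- rep(seq_len(n_slots), each = n_res)
  aa <- unlist(res, use.names = FALSE)
  if (any(!aa %in% rownames(params$contact_table))) {
    stop("contact table missing entries for residue(s): ",
         paste(setdiff(aa, rownames(params$contact_table)), collapse = ", "))
  }
  q <- RESIDUE_CHARGE[aa]
  eps_class <- params$dielectric_by_class[residue_polarity_class(aa)]

  d <- as.matrix(stats::dist(all_cent))
  inter <- outer(chain_of, chain_of, "!=")
  upper <- upper.tri(d)
  sel_contact <- inter & upper & d <= params$contact_cutoff
  ij <- which(sel_contact, arr.ind = TRUE)
  e_contact <- if (nrow(ij)) {
    sum(params$contact_table[cbind(aa[ij[, 1]], aa[ij[, 2]])])
  } else 0

  qq <- outer(q, q)
  sel_elec <- inter & upper & qq != 0
  ij2 <- which(sel_elec, arr.ind = TRUE)
  e_elec <- if (nrow(ij2)) {
    eps_ij <- pmax(eps_class[ij2[, 1]], eps_class[ij2[, 2]])
    sum(params$coulomb_constant * qq[sel_elec] /
          (eps_ij * d[sel_elec]))
  } else 0

  e_desolv <- params$desolvation_penalty *
    buried_charged_count(scaffold, res, cent, params)

  comps <- c(hbond = e_hbond, contact = e_contact,
             electrostatic = e_elec, desolvation = e_desolv)
  total <- sum(comps)
  list(dg = total / n_slots, total = total, components = comps)
}

#' Aggregation-propensity model parameters
#'
#' @param hydropathy_scale,beta_scale named per-residue scales.
#' @param weight_hydropathy,weight_beta,weight_charge nonnegative weights
#'   of the three profile terms.
#' @param window moving-average window (residues, >= 1).
#' @param gain,offset affine normalization applied to the profile mean.
#' @return object of class \code{aggregation_params}.
#' @export
aggregation_params <- function(hydropathy_scale = KD_HYDROPATHY,
                               beta_scale = BETA_PROPENSITY,
                               weight_hydropathy = 1, weight_beta = 1,
                               weight_charge = 1, window = 5,
                               gain = 0.25, offset = 0) {
  stopifnot(window >= 1)
  structure(list(hydropathy_scale = hydropathy_scale,
                 beta_scale = beta_scale,
                 weight_hydropathy = weight_hydropathy,
                 weight_beta = weight_beta, weight_charge = weight_charge,
                 window = window, gain = gain, offset = offset),
            class = "aggregation_params")
}

moving_average <- function(x, window) {
  h <- (window - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Intrinsic self-aggregation propensity of a single peptide
#'
#' Per-residue profile \code{z_i = w_h * hydropathy_i + w_b * beta_i -
#' w_c * |charge_i|}, moving-averaged over \code{window} residues
#' (truncated at the termini), averaged over positions, then mapped through
#' the affine normalization \code{gain * mean + offset}. Lower values mean
#' a weaker self-assembly tendency.
#'
#' @param seq peptide sequence (one-letter string).
#' @param params an \code{\link{aggregation_params}} object.
#' @return dimensionless propensity (scalar).
#' @export
aggregation_propensity <- function(seq, params = aggregation_params()) {
  chars <- seq_chars(seq)
  if (!all(chars %in% AA20)) stop("non-standard residue in sequence")
  miss <- setdiff(chars, intersect(names(params$hydropathy_scale),
                                   names(params$beta_scale)))
  if (length(miss)) {
    stop("scale missing residue(s): ", paste(miss, collapse = ", "))
  }
  if (params$window > length(chars)) {
    stop("window exceeds sequence length")
  }
  z <- params$weight_hydropathy * params$hydropathy_scale[chars] +
    params$weight_beta * params$beta_scale[chars] -
    params$weight_charge * abs(RESIDUE_CHARGE[chars])
  params$gain * mean(moving_average(as.numeric(z), params$window)) +
    params$offset
}

#' Full score breakdown for a peptide pair
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @param scaffold a \code{fibril_scaffold}.
#' @param e_params an \code{\link{energy_params}} object.
#' @param a_params an \code{\link{aggregation_params}} object.
#' @param lambda_weight score weighting factor.
#' @return object of class \code{score_breakdown} with fields
#'   \code{dg_binding}, \code{p_agg} (mean of the two chains),
#'   \code{p_agg_A}, \code{p_agg_B}, \code{lambda}, \code{gamma} and
#'   \code{components}.
#' @export
score_pair <- function(pair, scaffold, e_params = energy_params(),
                       a_params = aggregation_params(),
                       lambda_weight = 4.0) {
  be <- binding_energy(pair, scaffold, e_params)
  pa <- aggregation_propensity(pair$seq_A, a_params)
  pb <- aggregation_propensity(pair$seq_B, a_params)
  p_agg <- (pa + pb) / 2
  structure(list(dg_binding = be$dg, p_agg = p_agg,
                 p_agg_A = pa, p_agg_B = pb, lambda = lambda_weight,
                 gamma = combine_score(be$dg, p_agg, lambda_weight),
                 components = be$components),
            class = "score_breakdown")
}

#' @export
print.score_breakdown <- function(x, ...) {
  cat(sprintf("Design score (lambda = %.1f)\n", x$lambda))
  cat(sprintf("  gamma      %8.3f kcal/mol\n", x$gamma))
  cat(sprintf("  dG_binding %8.3f kcal/mol per peptide\n", x$dg_binding))
  cat(sprintf("  P_agg      %8.3f (A %.3f, B %.3f)\n",
              x$p_agg, x$p_agg_A, x$p_agg_B))
  cat("  components (kcal/mol):",
      paste(sprintf("%s %.2f", names(x$components), x$components),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.score_breakdown <- function(object, ...) {
  c(gamma = object$gamma, dg_binding = object$dg_binding,
    p_agg = object$p_agg, lambda = object$lambda)
}
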