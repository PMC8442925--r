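## Idealized two-layer antiparallel beta-sheet fibril scaffold.
##
## Strands are straight (no twist or pleat of the backbone trace); each
## sheet is a stack of strands 4.8 A apart, the two sheets face each other
## 10 A apart, and side-chain centroids are placed along the sheet normal
## with beta-pleat parity (even 1-based positions face the opposing sheet).
## Only relative distances enter the downstream energy, so the idealization
## is sufficient for a fixed-backbone design.

#' Scaffold geometry parameters
#'
#' @param strand_spacing inter-strand distance within a sheet (Angstrom).
#' @param sheet_separation distance between the two sheet planes (Angstrom).
#' @param ca_spacing Calpha-Calpha distance along a strand (Angstrom).
#' @param n_strands_per_sheet,n_sheets fibril size.
#' @param n_residues residues per strand.
#' @return object of class \code{scaffold_geometry}.
#' @export
scaffold_geometry <- function(strand_spacing = 4.8, sheet_separation = 10.0,
                              ca_spacing = 3.5, n_strands_per_sheet = 6,
                              n_sheets = 2, n_residues = 11) {
  stopifnot(strand_spacing > 0, sheet_separation > 0, ca_spacing > 0,
            n_sheets >= 1, n_strands_per_sheet >= 1, n_residues >= 2)
  structure(list(strand_spacing = strand_spacing,
                 sheet_separation = sheet_separation,
                 ca_spacing = ca_spacing,
                 n_strands_per_sheet = n_strands_per_sheet,
                 n_sheets = n_sheets, n_residues = n_residues),
            class = "scaffold_geometry")
}

#' Build the idealized fibril scaffold
#'
#' Within each sheet adjacent strands alternate orientation (antiparallel);
#' strands in register across sheets share orientation (parallel between
#' sheets); chain species alternate A,B,A,B,... along each sheet. All three
#' choices are option-controlled.
#'
#' @param geometry a \code{\link{scaffold_geometry}}.
#' @param antiparallel_within,parallel_across,alternate_species logical
#'   switches for the default architecture.
#' @return object of class \code{fibril_scaffold} with components
#'   \code{slots} (data.frame: sheet, strand, orientation, species,
#'   chain_id), \code{ca} (list of n_residues x 3 matrices),
#'   \code{sc_dir} (list of unit side-chain direction matrices),
#'   \code{hbond_registry} (data.frame: slot_i, slot_j, n_hbonds) and
#'   \code{geometry}.
#' @examples
#' sc <- build_scaffold(scaffold_geometry())
#' nrow(sc$slots)  # 12 peptide slots
#' @export
build_scaffold <- function(geometry = scaffold_geometry(),
                           antiparallel_within = TRUE,
                           parallel_across = TRUE,
                           alternate_species = TRUE) {
  g <- geometry
  if (alternate_species && g$n_strands_per_sheet < 2) {
    stop("species alternation requires at least 2 strands per sheet")
  }
  n_slots <- g$n_sheets * g$n_strands_per_sheet
  if (n_slots > 52) stop("at most 52 slots supported (chain id alphabet)")
  chain_ids <- c(LETTERS, letters)[seq_len(n_slots)]

  slots <- data.frame(sheet = integer(0), strand = integer(0),
                      orientation = integer(0), species = character(0),
                      chain_id = character(0), stringsAsFactors = FALSE)
  ca <- list(); sc_dir <- list()
  k <- 0L
  sheet_z <- (seq_len(g$n_sheets) - 1) * g$sheet_separation
  mid_z <- mean(sheet_z)
  for (s in seq_len(g$n_sheets)) {
    for (t in seq_len(g$n_strands_per_sheet)) {
      k <- k + 1L
      ori <- 1L
      if (antiparallel_within && t %% 2 == 0) ori <- -1L
      if (!parallel_across && s %% 2 == 0) ori <- -ori
      species <- if (alternate_species && t %% 2 == 0) "B" else "A"
      i <- seq_len(g$n_residues)
      ## residue positions along x; reversed strands run N->C along -x
      x <- if (ori == 1L) (i - 1) * g$ca_spacing else
        (g$n_residues - i) * g$ca_spacing
      pos <- cbind(x = x, y = (t - 1) * g$strand_spacing,
                   z = sheet_z[s])
      ## side chains alternate up/down along the sheet normal; even
      ## 1-based positions face the opposing sheet (the zipper interface)
      inward <- if (g$n_sheets == 1) 1 else sign(mid_z - sheet_z[s])
      if (inward == 0) inward <- 1
      parity <- ifelse(i %% 2 == 0, 1, -1) * inward
      dirs <- cbind(x = 0, y = 0, z = parity)
      slots <- rbind(slots, data.frame(
        sheet = s, strand = t, orientation = ori, species = species,
        chain_id = chain_ids[k], stringsAsFactors = FALSE))
      ca[[k]] <- pos
      sc_dir[[k]] <- dirs
    }
  }

  ## backbone hydrogen-bond registry: adjacent strands within each sheet
  reg <- NULL
  idx <- function(s, t) (s - 1L) * g$n_strands_per_sheet + t
  for (s in seq_len(g$n_sheets)) {
    for (t in seq_len(g$n_strands_per_sheet - 1L)) {
      reg <- rbind(reg, data.frame(slot_i = idx(s, t),
                                   slot_j = idx(s, t + 1L),
                                   n_hbonds = g$n_residues))
    }
  }
  if (is.null(reg)) {
    reg <- data.frame(slot_i = integer(0), slot_j = integer(0),
                      n_hbonds = integer(0))
  }
  structure(list(slots = slots, ca = ca, sc_dir = sc_dir,
                 hbond_registry = reg, geometry = g),
            class = "fibril_scaffold")
}

#' @export
print.fibril_scaffold <- function(x, ...) {
  g <- x$geometry
  cat(sprintf("Fibril scaffold: %d sheet(s) x %d strand(s), %d residues/strand\n",
              g$n_sheets, g$n_strands_per_sheet, g$n_residues))
  cat(sprintf("  strand spacing %.1f A, sheet separation %.1f A, Ca spacing %.1f A\n",
              g$strand_spacing, g$sheet_separation, g$ca_spacing))
  cat("  species per sheet:",
      paste(x$slots$species[x$slots$sheet == 1], collapse = ","), "\n")
  invisible(x)
}

## Thread a peptide pair onto the scaffold: per-slot residue vectors.
thread_sequences <- function(scaffold, pair) {
  n <- scaffold$geometry$n_residues
  a <- seq_chars(pair$seq_A); b <- seq_chars(pair$seq_B)
  if (length(a) != n || length(b) != n) {
    stop("sequence length does not match scaffold strand length")
  }
  lapply(scaffold$slots$species, function(sp) if (sp == "A") a else b)
}

#' Side-chain centroid coordinates for a threaded pair
#'
#' Centroids are placed along each slot's side-chain direction at the
#' residue's canonical extent.
#'
#' @param scaffold a \code{\link{build_scaffold}} result.
#' @param pair a \code{\link{peptide_pair}} threaded by slot species.
#' @param extent named per-residue Calpha-to-centroid distances (Angstrom).
#' @return list of n_residues x 3 matrices, one per slot.
#' @export
sidechain_centroids <- function(scaffold, pair,
                                extent = SIDECHAIN_EXTENT) {
  res <- thread_sequences(scaffold, pair)
  lapply(seq_along(scaffold$ca), function(k) {
    d <- extent[res[[k]]]
    scaffold$ca[[k]] + scaffold$sc_dir[[k]] * d
  })
}

#' Apply a rigid motion to a scaffold
#'
#' Rotates and translates all backbone coordinates and rotates the
#' side-chain direction vectors; every distance-based quantity downstream
#' is unchanged.
#'
#' @param scaffold a \code{fibril_scaffold}.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return transformed \code{fibril_scaffold}.
#' @export
transform_scaffold <- function(scaffold, rotation = diag(3),
                               translation = c(0, 0, 0)) {
  scaffold$ca <- lapply(scaffold$ca, function(m) {
    sweep(m %*% t(rotation), 2, translation, "+")
  })
  scaffold$sc_dir <- lapply(scaffold$sc_dir, function(m) m %*% t(rotation))
  scaffold
}

#' Write a threaded scaffold as a PDB file
#'
#' One chain per slot; CA atoms carry the backbone trace and CB
#' pseudo-atoms the side-chain centroids so the file parses under standard
#' PDB readers.
#'
#' @param scaffold a \code{fibril_scaffold}.
#' @param pair the \code{\link{peptide_pair}} to thread.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_scaffold_pdb <- function(scaffold, pair, path) {
  res <- thread_sequences(scaffold, pair)
  cent <- sidechain_centroids(scaffold, pair)
  n <- scaffold$geometry$n_residues
  xyz <- NULL; elety <- character(0); resid <- character(0)
  resno <- integer(0); chain <- character(0)
  for (k in seq_along(scaffold$ca)) {
    for (i in seq_len(n)) {
      aa3 <- AA3[res[[k]][i]]
      has_sc <- res[[k]][i] != "G"
      xyz <- rbind(xyz, scaffold$ca[[k]][i, , drop = FALSE])
      elety <- c(elety, "CA"); resid <- c(resid, aa3)
      resno <- c(resno, i); chain <- c(chain, scaffold$slots$chain_id[k])
      if (has_sc) {
        xyz <- rbind(xyz, cent[[k]][i, , drop = FALSE])
        elety <- c(elety, "CB"); resid <- c(resid, aa3)
        resno <- c(resno, i); chain <- c(chain, scaffold$slots$chain_id[k])
      }
    }
  }
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", length(elety)),
                   resno = resno, resid = resid, eleno = seq_along(elety),
                   elety = elety, chain = chain,
                   o = rep(1, length(elety)), b = rep(0, length(elety)))
  invisible(path)
}
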