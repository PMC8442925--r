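## Constrained sequence space for charge-complementary 11-mer design:
## an HP pattern fixes which sites are hydrophobic, composition rules fix
## how many polar and charged residues occupy the P sites, and each chain
## carries charges of a single sign (A cationic, B anionic).

#' Residue class table
#'
#' Partitions the 20 standard amino acids into the classes used by the
#' design constraints: hydrophobic (legal at H sites), polar and charged
#' (legal at P sites), and excluded residues that may not appear at all.
#' Cysteine, proline and glycine are always excluded.
#'
#' @param hydrophobic,polar,positive,negative,excluded character vectors of
#'   one-letter codes. The five sets must be pairwise disjoint.
#' @return an object of class \code{residue_classes}.
#' @examples
#' tab <- residue_classes()
#' classify_residue("K", tab)
#' @export
residue_classes <- function(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
                            polar = c("S", "T", "N", "Q"),
                            positive = c("K", "R"),
                            negative = c("D", "E"),
                            excluded = c("C", "P", "G")) {
  sets <- list(hydrophobic = hydrophobic, polar = polar,
               positive = positive, negative = negative,
               excluded = excluded)
  all_codes <- unlist(sets, use.names = FALSE)
  if (!all(all_codes %in% AA20)) {
    stop("non-standard residue code(s): ",
         paste(setdiff(all_codes, AA20), collapse = ", "))
  }
  if (anyDuplicated(all_codes)) {
    stop("residue class sets must be pairwise disjoint; duplicated: ",
         paste(unique(all_codes[duplicated(all_codes)]), collapse = ", "))
  }
  if (!all(c("C", "P", "G") %in% excluded)) {
    stop("excluded set must contain C, P and G")
  }
  structure(sets, class = "residue_classes")
}

#' @export
print.residue_classes <- function(x, ...) {
  cat("Residue classes:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-11s %s\n", nm, paste(x[[nm]], collapse = " ")))
  }
  invisible(x)
}

#' Classify a single residue
#'
#' @param code one-letter residue code.
#' @param table a \code{\link{residue_classes}} object.
#' @return one of \code{"hydrophobic"}, \code{"polar"}, \code{"positive"},
#'   \code{"negative"}, \code{"excluded"}, or \code{"unassigned"} for a
#'   standard residue not placed in any set.
#' @export
classify_residue <- function(code, table = residue_classes()) {
  if (length(code) != 1L || !code %in% AA20) {
    stop("unknown residue code: ", paste(code, collapse = ""))
  }
  for (nm in names(table)) {
    if (code %in% table[[nm]]) return(nm)
  }
  "unassigned"
}

#' Hydrophobic/polar sequence pattern
#'
#' The default, \code{"PPPHPHPHPPP"}, places hydrophobic sites at positions
#' 4, 6 and 8 of an 11-mer, the pattern shared by the CATCH-style
#' charge-complementary peptides.
#'
#' @param pattern string over the alphabet \code{{H, P}}.
#' @return object of class \code{sequence_pattern}.
#' @export
sequence_pattern <- function(pattern = "PPPHPHPHPPP") {
  chars <- strsplit(pattern, "")[[1]]
  if (!length(chars) || !all(chars %in% c("H", "P"))) {
    stop("pattern must be a non-empty string over {H, P}")
  }
  structure(list(pattern = pattern, sites = chars,
                 h_sites = which(chars == "H"),
                 p_sites = which(chars == "P")),
            class = "sequence_pattern")
}

#' @export
print.sequence_pattern <- function(x, ...) {
  cat("HP pattern:", x$pattern,
      sprintf("(%d H sites, %d P sites)\n",
              length(x$h_sites), length(x$p_sites)))
  invisible(x)
}

#' Composition constraint
#'
#' Default: three hydrophobic, three polar and five charged residues per
#' chain, with net side-chain charge +5 on peptide A and -5 on peptide B
#' (termini treated as capped and uncharged).
#'
#' @param n_hydrophobic,n_polar,n_charged residue counts per chain.
#' @param charge_A,charge_B net formal charges of peptides A and B.
#' @return object of class \code{composition_constraint}.
#' @export
composition_constraint <- function(n_hydrophobic = 3, n_polar = 3,
                                   n_charged = 5,
                                   charge_A = 5, charge_B = -5) {
  if (abs(charge_A) != n_charged || abs(charge_B) != n_charged) {
    stop("single-sign chains require |charge| to equal n_charged")
  }
  if (charge_A <= 0 || charge_B >= 0) {
    stop("peptide A must be net positive and peptide B net negative")
  }
  structure(list(n_hydrophobic = n_hydrophobic, n_polar = n_polar,
                 n_charged = n_charged,
                 charge_A = charge_A, charge_B = charge_B),
            class = "composition_constraint")
}

#' A pair of designed peptide sequences
#'
#' @param seq_A,seq_B peptide sequences as one-letter strings (A is the
#'   cationic chain, B the anionic chain).
#' @return object of class \code{peptide_pair}.
#' @export
peptide_pair <- function(seq_A, seq_B) {
  for (s in c(seq_A, seq_B)) {
    chars <- strsplit(s, "")[[1]]
    if (!all(chars %in% AA20)) {
      stop("sequence contains non-standard residue(s): ", s)
    }
  }
  structure(list(seq_A = seq_A, seq_B = seq_B), class = "peptide_pair")
}

#' @export
print.peptide_pair <- function(x, ...) {
  cat("Peptide pair:\n  A (+):", x$seq_A, "\n  B (-):", x$seq_B, "\n")
  invisible(x)
}

seq_chars <- function(s) strsplit(s, "")[[1]]

## Charged set legal on a given chain.
chain_charged_set <- function(chain, table) {
  if (chain == "A") table$positive else table$negative
}

validate_chain <- function(seq, chain, pattern, comp, table) {
  violations <- character(0)
  chars <- seq_chars(seq)
  n <- length(pattern$sites)
  if (length(chars) != n) {
    stop("sequence length ", length(chars), " does not match pattern length ",
         n, " (chain ", chain, ")")
  }
  bad <- intersect(chars, table$excluded)
  if (length(bad)) {
    violations <- c(violations, paste0("chain ", chain,
                                       ": excluded residue(s) ",
                                       paste(unique(bad), collapse = ", ")))
  }
  classes <- vapply(chars, classify_residue, character(1), table = table)
  ## H sites must hold hydrophobic residues
  h_bad <- pattern$h_sites[classes[pattern$h_sites] != "hydrophobic"]
  if (length(h_bad)) {
    violations <- c(violations, paste0("chain ", chain,
                                       ": non-hydrophobic residue at H site(s) ",
                                       paste(h_bad, collapse = ", ")))
  }
  ## P sites must hold polar residues or charges of the chain's sign
  legal_charge_class <- if (chain == "A") "positive" else "negative"
  p_cls <- classes[pattern$p_sites]
  p_bad <- pattern$p_sites[!(p_cls %in% c("polar", legal_charge_class))]
  if (length(p_bad)) {
    violations <- c(violations, paste0("chain ", chain,
                                       ": illegal residue class at P site(s) ",
                                       paste(p_bad, collapse = ", ")))
  }
  ## composition counts
  n_h <- sum(classes == "hydrophobic")
  n_p <- sum(classes == "polar")
  n_c <- sum(classes %in% c("positive", "negative"))
  if (n_h != comp$n_hydrophobic) {
    violations <- c(violations, sprintf(
      "chain %s: %d hydrophobic residues, expected %d", chain, n_h,
      comp$n_hydrophobic))
  }
  if (n_p != comp$n_polar) {
    violations <- c(violations, sprintf(
      "chain %s: %d polar residues, expected %d", chain, n_p, comp$n_polar))
  }
  if (n_c != comp$n_charged) {
    violations <- c(violations, sprintf(
      "chain %s: %d charged residues, expected %d", chain, n_c,
      comp$n_charged))
  }
  ## net charge
  q <- sum(RESIDUE_CHARGE[chars])
  want <- if (chain == "A") comp$charge_A else comp$charge_B
  if (q != want) {
    violations <- c(violations, sprintf(
      "chain %s: net charge %+d, expected %+d", chain, q, want))
  }
  violations
}

#' Validate a peptide pair against the design constraints
#'
#' A pair passes when, on each chain, every H site holds a hydrophobic
#' residue, every P site a polar or (sign-legal) charged residue, the
#' composition counts match, the net charges equal the constraint, and no
#' excluded residue appears.
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @param pattern a \code{\link{sequence_pattern}}.
#' @param comp a \code{\link{composition_constraint}}.
#' @param table a \code{\link{residue_classes}} table.
#' @return list with elements \code{pass} (logical) and \code{violations}
#'   (character vector), class \code{pair_validation}.
#' @examples
#' validate_pair(peptide_pair("KKKVKVKVNTT", "TNTAEFEFEED"))
#' @export
validate_pair <- function(pair, pattern = sequence_pattern(),
                          comp = composition_constraint(),
                          table = residue_classes()) {
  v <- c(validate_chain(pair$seq_A, "A", pattern, comp, table),
         validate_chain(pair$seq_B, "B", pattern, comp, table))
  structure(list(pass = length(v) == 0L, violations = v),
            class = "pair_validation")
}

#' @export
print.pair_validation <- function(x, ...) {
  if (x$pass) {
    cat("PASS: pair satisfies all design constraints\n")
  } else {
    cat("FAIL:", length(x$violations), "violation(s)\n")
    for (v in x$violations) cat("  -", v, "\n")
  }
  invisible(x)
}

random_chain <- function(chain, pattern, comp, table) {
  charged_set <- chain_charged_set(chain, table)
  n_p <- length(pattern$p_sites)
  if (comp$n_charged > n_p) {
    stop("infeasible constraints: n_charged exceeds number of P sites")
  }
  if (comp$n_polar != n_p - comp$n_charged) {
    stop("infeasible constraints: n_polar must equal #P sites - n_charged")
  }
  if (comp$n_hydrophobic != length(pattern$h_sites)) {
    stop("infeasible constraints: n_hydrophobic must equal #H sites")
  }
  if (!length(table$hydrophobic) || !length(table$polar) ||
      !length(charged_set)) {
    stop("infeasible constraints: empty residue class set")
  }
  chars <- character(length(pattern$sites))
  chars[pattern$h_sites] <- sample(table$hydrophobic,
                                   length(pattern$h_sites), replace = TRUE)
  charged_sites <- sample(pattern$p_sites, comp$n_charged)
  polar_sites <- setdiff(pattern$p_sites, charged_sites)
  chars[charged_sites] <- sample(charged_set, comp$n_charged, replace = TRUE)
  chars[polar_sites] <- sample(table$polar, length(polar_sites),
                               replace = TRUE)
  paste(chars, collapse = "")
}

#' Draw a random valid peptide pair
#'
#' @inheritParams validate_pair
#' @param seed optional integer; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @return a \code{\link{peptide_pair}} passing \code{\link{validate_pair}}.
#' @export
random_pair <- function(pattern = sequence_pattern(),
                        comp = composition_constraint(),
                        table = residue_classes(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  peptide_pair(random_chain("A", pattern, comp, table),
               random_chain("B", pattern, comp, table))
}

#' Size of the admissible sequence space
#'
#' Exact combinatorial count of single-chain sequences and of A-B pairs:
#' per chain, the product of per-site alphabet sizes summed over the
#' placements of charged residues among the P sites, i.e.
#' \code{choose(nP, n_charged) * |charged|^n_charged * |polar|^n_polar *
#' |hydrophobic|^nH}.
#'
#' @inheritParams validate_pair
#' @return list with \code{per_chain_A}, \code{per_chain_B} and
#'   \code{pairs} counts (numeric; may exceed integer range).
#' @export
enumerate_space_size <- function(pattern = sequence_pattern(),
                                 comp = composition_constraint(),
                                 table = residue_classes()) {
  n_p <- length(pattern$p_sites)
  n_h <- length(pattern$h_sites)
  chain_count <- function(charged_set) {
    choose(n_p, comp$n_charged) *
      length(charged_set)^comp$n_charged *
      length(table$polar)^comp$n_polar *
      length(table$hydrophobic)^n_h
  }
  a <- chain_count(table$positive)
  b <- chain_count(table$negative)
  list(per_chain_A = a, per_chain_B = b, pairs = a * b)
}
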