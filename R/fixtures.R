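## Fixture generators: every module is testable from code-built inputs.

#' Published reference sequences and scores
#'
#' The six computationally discovered charge-complementary 11-mer pairs
#' (designs 1-6) with their reported per-peptide binding free energies,
#' aggregation propensities, weighting factors and combined scores, plus
#' the previously published CATCH, Q11 and King-Webb peptides used as
#' comparators.
#'
#' @return data.frame with columns name, role, chain, sequence, lambda,
#'   gamma, dg, p_agg (score columns NA for the comparator peptides).
#' @export
reference_sequences <- function() {
  d <- data.frame(
    name = rep(paste0("design", 1:6), each = 2),
    role = "design",
    chain = rep(c("A", "B"), 6),
    sequence = c("KKKMKVKVNTT", "TNTADFEFEED",
                 "KKKVKVKFTTN", "TNTVDFEYEED",
                 "KKKWKMKATNT", "TNTVEVELDDD",
                 "KKKVKVKVNTT", "TNTAEFEFEED",
                 "KKKVKVKVNTT", "TNTMDFEYEED",
                 "KKKVKYTFKNT", "TNTMEVDFDED"),
    lambda = rep(c(3.0, 3.0, 3.0, 4.0, 4.0, 4.0), each = 2),
    gamma = rep(c(-25.40, -25.35, -26.85, -25.62, -25.80, -25.93),
                each = 2),
    dg = rep(c(-25.07, -24.93, -25.87, -25.16, -25.62, -25.21),
             each = 2),
    p_agg = rep(c(-0.11, -0.14, -0.33, -0.12, -0.05, -0.18), each = 2),
    stringsAsFactors = FALSE)
  cmp <- data.frame(
    name = c("CATCH_4plus", "CATCH_6minus", "Q11", "KW_plus", "KW_minus"),
    role = "comparator",
    chain = c("A", "B", "A", "A", "B"),
    sequence = c("QQKFKFKFKQQ", "EQEFEFEFEQE", "QQKFQFKQEQQ",
                 "KKFEWEFEKK", "EEFKWKFKEE"),
    lambda = NA_real_, gamma = NA_real_, dg = NA_real_,
    p_agg = NA_real_, stringsAsFactors = FALSE)
  rbind(d, cmp)
}

#' The peptide pair of a named reference design
#'
#' @param name design name, e.g. \code{"design4"}.
#' @return a \code{\link{peptide_pair}}.
#' @export
reference_pair <- function(name) {
  tab <- reference_sequences()
  sel <- tab[tab$name == name, ]
  if (nrow(sel) != 2) stop("unknown design name: ", name)
  peptide_pair(sel$sequence[sel$chain == "A"],
               sel$sequence[sel$chain == "B"])
}

## Add Gaussian coordinate noise to every chain of a frame.
perturb_frame <- function(frame, sd) {
  frame$chains <- lapply(frame$chains, function(ch) {
    ch$ca <- ch$ca + matrix(stats::rnorm(length(ch$ca), 0, sd),
                            ncol = 3)
    ch
  })
  frame
}

#' Generate a test fixture on disk
#'
#' Kinds: \code{ideal_fibril} (threaded 2x6 scaffold PDB),
#' \code{noisy_fibril} (same with Gaussian coordinate noise),
#' \code{mixed_dispersed} (half the chains in a scaffold, half dispersed),
#' \code{synthetic_spectrum} (two reporter peaks at a known A:B ratio) and
#' \code{reference_sequences} (FASTA of the published sequences). Each
#' fixture writes a JSON sidecar with its ground truth. Deterministic per
#' seed.
#'
#' @param kind fixture kind.
#' @param dir output directory (created if needed).
#' @param params kind-specific parameter list; see Details in the source.
#' @param seed RNG seed.
#' @return named list of written file paths, invisibly.
#' @export
make_fixture <- function(kind, dir, params = list(), seed = 1) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(seed)
  get_par <- function(nm, default) {
    if (!is.null(params[[nm]])) params[[nm]] else default
  }
  pair <- get_par("pair", reference_pair("design4"))
  files <- switch(
    kind,
    ideal_fibril = {
      sc <- build_scaffold(scaffold_geometry(
        n_strands_per_sheet = get_par("n_strands_per_sheet", 6),
        n_sheets = get_par("n_sheets", 2)))
      pdb <- file.path(dir, "ideal_fibril.pdb")
      write_scaffold_pdb(sc, pair, pdb)
      side <- file.path(dir, "ideal_fibril.json")
      jsonlite::write_json(list(
        n_chains = nrow(sc$slots),
        n_sheets = sc$geometry$n_sheets,
        within_sheet_orientation = "antiparallel",
        cross_sheet_orientation = "parallel",
        within_sheet_nearest_species = "AB",
        composition_ratio = 1.0, beta_content = 1.0),
        side, auto_unbox = TRUE)
      list(pdb = pdb, sidecar = side)
    },
    noisy_fibril = {
      sc <- build_scaffold(scaffold_geometry(
        n_strands_per_sheet = get_par("n_strands_per_sheet", 6),
        n_sheets = get_par("n_sheets", 2)))
      sd <- get_par("noise_sd", 0.3)
      fr <- perturb_frame(scaffold_to_frame(sc), sd)
      ## write via a temporary scaffold carrying the noisy coordinates
      sc$ca <- lapply(fr$chains, function(ch) ch$ca)
      pdb <- file.path(dir, "noisy_fibril.pdb")
      write_scaffold_pdb(sc, pair, pdb)
      side <- file.path(dir, "noisy_fibril.json")
      jsonlite::write_json(list(
        n_chains = nrow(sc$slots), n_sheets = sc$geometry$n_sheets,
        noise_sd = sd, composition_ratio = 1.0, beta_content = 1.0),
        side, auto_unbox = TRUE)
      list(pdb = pdb, sidecar = side)
    },
    mixed_dispersed = {
      sc <- build_scaffold(scaffold_geometry(
        n_strands_per_sheet = get_par("n_strands_per_sheet", 6),
        n_sheets = get_par("n_sheets", 2)))
      fr <- scaffold_to_frame(sc)
      n <- length(fr$chains)
      ## displace the second half of the chains far apart
      for (k in seq(n %/% 2 + 1, n)) {
        fr$chains[[k]]$ca <- fr$chains[[k]]$ca +
          matrix(rep(c(500 * k, 500 * k, 0), each = nrow(fr$chains[[k]]$ca)),
                 ncol = 3)
      }
      sc$ca <- lapply(fr$chains, function(ch) ch$ca)
      pdb <- file.path(dir, "mixed_dispersed.pdb")
      write_scaffold_pdb(sc, pair, pdb)
      side <- file.path(dir, "mixed_dispersed.json")
      jsonlite::write_json(list(n_chains = n, beta_content = 0.5),
                           side, auto_unbox = TRUE)
      list(pdb = pdb, sidecar = side)
    },
    synthetic_spectrum = {
      ratio <- get_par("ratio", 2.0)
      mult <- get_par("multiplicities", reporter_multiplicities(pair))
      area_E <- get_par("area_E", 1.0)
      area_K <- ratio * area_E * mult[["n_K_per_A"]] / mult[["n_E_per_B"]]
      peaks <- data.frame(center = c(23.0, 181.0),
                          fwhm = get_par("fwhm", c(0.6, 0.5)),
                          area = c(area_K, area_E))
      sp <- synth_spectrum(peaks, ppm_range = c(0, 200),
                           n_points = get_par("n_points", 8000),
                           noise_sd = get_par("noise_sd", 0))
      csv <- file.path(dir, "synthetic_spectrum.csv")
      utils::write.csv(data.frame(ppm = sp$ppm, intensity = sp$intensity),
                       csv, row.names = FALSE)
      side <- file.path(dir, "synthetic_spectrum.json")
      jsonlite::write_json(list(
        true_ratio = ratio, peaks = peaks,
        multiplicities = as.list(mult)), side, auto_unbox = TRUE)
      list(csv = csv, sidecar = side)
    },
    reference_sequences = {
      tab <- reference_sequences()
      fa <- file.path(dir, "reference_sequences.fasta")
      set <- Biostrings::AAStringSet(tab$sequence)
      names(set) <- paste0(tab$name, "_", tab$chain,
                           " /chain=", tab$chain)
      Biostrings::writeXStringSet(set, fa)
      side <- file.path(dir, "reference_sequences.json")
      jsonlite::write_json(tab, side)
      list(fasta = fa, sidecar = side)
    },
    stop("unknown fixture kind: ", kind))
  invisible(files)
}
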