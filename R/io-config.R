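## Shared I/O: FASTA via Biostrings, YAML design configuration with
## strict key checking.

#' Read peptide sequences from FASTA
#'
#' @param path FASTA file.
#' @return named list of sequence strings.
#' @export
read_fasta_sequences <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.list(as.character(set)), names(set))
}

#' Write a peptide pair to FASTA
#'
#' The pair is stored as two records whose description lines carry
#' \code{/chain=A} and \code{/chain=B} tags.
#'
#' @param pair a \code{\link{peptide_pair}}.
#' @param path output path.
#' @param id record id prefix.
#' @return \code{path}, invisibly.
#' @export
write_pair_fasta <- function(pair, path, id = "design") {
  set <- Biostrings::AAStringSet(c(pair$seq_A, pair$seq_B))
  names(set) <- c(paste0(id, "_A /chain=A"), paste0(id, "_B /chain=B"))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a peptide pair from FASTA
#'
#' Chains are identified by \code{/chain=A|B} tags in the description
#' lines; without tags, the first record is taken as chain A and the
#' second as chain B.
#'
#' @param path FASTA file with two records.
#' @return a \code{\link{peptide_pair}}.
#' @export
read_pair_fasta <- function(path) {
  seqs <- read_fasta_sequences(path)
  if (length(seqs) != 2) stop("pair FASTA must contain exactly 2 records")
  tags <- regmatches(names(seqs), regexpr("/chain=[AB]", names(seqs)))
  if (length(tags) == 2) {
    a <- seqs[[which(grepl("/chain=A", names(seqs), fixed = TRUE))]]
    b <- seqs[[which(grepl("/chain=B", names(seqs), fixed = TRUE))]]
  } else {
    a <- seqs[[1]]; b <- seqs[[2]]
  }
  peptide_pair(a, b)
}

#' Default design configuration
#'
#' A nested list covering every tunable block: sequence constraints,
#' energy and aggregation model parameters, MC settings, scaffold
#' geometry, and analysis cutoffs. Serializable to YAML.
#'
#' @return nested list of class \code{design_config}.
#' @export
design_config <- function() {
  structure(list(
    constraints = list(
      pattern = "PPPHPHPHPPP",
      n_hydrophobic = 3, n_polar = 3, n_charged = 5,
      charge_A = 5, charge_B = -5,
      hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "Y"),
      polar = c("S", "T", "N", "Q"),
      positive = c("K", "R"), negative = c("D", "E"),
      excluded = c("C", "P", "G")),
    energy = list(
      hbond_energy = -1.5, contact_cutoff = 6.5,
      coulomb_constant = 332.06,
      dielectric_nonpolar = 1, dielectric_polar = 2,
      dielectric_charged = 4,
      desolvation_penalty = 1.0, burial_margin = 0.0,
      contact_table_csv = ""),
    aggregation = list(
      weight_hydropathy = 1, weight_beta = 1, weight_charge = 1,
      window = 5, gain = 0.25, offset = 0),
    mc = list(
      n_steps = 2000, effective_temperature = 1.0,
      p_mutation = 0.5, p_intra_exchange = 0.25,
      p_inter_exchange = 0.25, lambda_weight = 4.0,
      report_stride = 1, n_best = 6, rng_seed = 1),
    scaffold = list(
      strand_spacing = 4.8, sheet_separation = 10.0, ca_spacing = 3.5,
      n_strands_per_sheet = 6, n_sheets = 2, n_residues = 11),
    analysis = list(
      in_sheet_cutoff = 5.5, registry_cutoff = 6.0,
      min_aligned = 4, cos_threshold = 0.5)),
    class = "design_config")
}

check_config_keys <- function(cfg, template, path = "") {
  unknown <- setdiff(names(cfg), names(template))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(cfg[[nm]])) next
      check_config_keys(cfg[[nm]], template[[nm]],
                        paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read a design configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to the defaults of
#' \code{\link{design_config}}.
#'
#' @param path YAML file.
#' @return a \code{design_config} list.
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  template <- design_config()
  check_config_keys(cfg, template)
  for (blk in names(cfg)) {
    for (key in names(cfg[[blk]])) {
      template[[blk]][[key]] <- cfg[[blk]][[key]]
    }
  }
  template
}

#' Write a design configuration as YAML
#'
#' @param config a \code{design_config} list.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_design_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## Instantiate module parameter objects from a config list.
config_objects <- function(cfg) {
  ct <- if (!is.null(cfg$energy$contact_table_csv) &&
            nzchar(cfg$energy$contact_table_csv)) {
    read_contact_table(cfg$energy$contact_table_csv)
  } else default_contact_table()
  list(
    pattern = sequence_pattern(cfg$constraints$pattern),
    comp = composition_constraint(cfg$constraints$n_hydrophobic,
                                  cfg$constraints$n_polar,
                                  cfg$constraints$n_charged,
                                  cfg$constraints$charge_A,
                                  cfg$constraints$charge_B),
    table = residue_classes(cfg$constraints$hydrophobic,
                            cfg$constraints$polar,
                            cfg$constraints$positive,
                            cfg$constraints$negative,
                            cfg$constraints$excluded),
    e_params = energy_params(
      hbond_energy = cfg$energy$hbond_energy,
      contact_table = ct,
      dielectric_by_class = c(nonpolar = cfg$energy$dielectric_nonpolar,
                              polar = cfg$energy$dielectric_polar,
                              charged = cfg$energy$dielectric_charged),
      coulomb_constant = cfg$energy$coulomb_constant,
      contact_cutoff = cfg$energy$contact_cutoff,
      desolvation_penalty = cfg$energy$desolvation_penalty,
      burial_margin = cfg$energy$burial_margin),
    a_params = aggregation_params(
      weight_hydropathy = cfg$aggregation$weight_hydropathy,
      weight_beta = cfg$aggregation$weight_beta,
      weight_charge = cfg$aggregation$weight_charge,
      window = cfg$aggregation$window,
      gain = cfg$aggregation$gain, offset = cfg$aggregation$offset),
    mc = mc_config(n_steps = cfg$mc$n_steps,
                   effective_temperature = cfg$mc$effective_temperature,
                   move_probabilities = c(cfg$mc$p_mutation,
                                          cfg$mc$p_intra_exchange,
                                          cfg$mc$p_inter_exchange),
                   rng_seed = cfg$mc$rng_seed,
                   lambda_weight = cfg$mc$lambda_weight,
                   report_stride = cfg$mc$report_stride,
                   n_best = cfg$mc$n_best),
    scaffold = build_scaffold(scaffold_geometry(
      strand_spacing = cfg$scaffold$strand_spacing,
      sheet_separation = cfg$scaffold$sheet_separation,
      ca_spacing = cfg$scaffold$ca_spacing,
      n_strands_per_sheet = cfg$scaffold$n_strands_per_sheet,
      n_sheets = cfg$scaffold$n_sheets,
      n_residues = cfg$scaffold$n_residues)))
}
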