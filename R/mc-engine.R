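## Metropolis Monte Carlo sequence evolution over the constrained pair
## space. Three moves perturb the sequences while preserving every
## constraint: intrachain residue mutation, intrachain residue exchange,
## and interchain residue exchange. Moves that lower the combined score
## are always accepted; uphill moves are accepted with probability
## exp(-delta/T) at a constant effective temperature.

#' Monte Carlo configuration
#'
#' @param n_steps number of MC steps (>= 1).
#' @param effective_temperature acceptance scale (kcal/mol, > 0).
#' @param move_probabilities probabilities of (mutation, intrachain
#'   exchange, interchain exchange); must sum to 1.
#' @param rng_seed integer seed; the whole run is reproducible from it.
#' @param lambda_weight score weighting factor.
#' @param report_stride steps between trace records.
#' @param n_best number of lowest-scoring distinct pairs to retain.
#' @param anneal_to optional final temperature for a linear schedule.
#' @return object of class \code{mc_config}.
#' @export
mc_config <- function(n_steps = 2000, effective_temperature = 1.0,
                      move_probabilities = c(mutation = 0.5,
                                             intra_exchange = 0.25,
                                             inter_exchange = 0.25),
                      rng_seed = 1, lambda_weight = 4.0,
                      report_stride = 1, n_best = 6, anneal_to = NULL) {
  stopifnot(n_steps >= 1, effective_temperature > 0,
            length(move_probabilities) == 3,
            all(move_probabilities >= 0),
            abs(sum(move_probabilities) - 1) <= 1e-12)
  names(move_probabilities) <- c("mutation", "intra_exchange",
                                 "inter_exchange")
  structure(list(n_steps = as.integer(n_steps),
                 effective_temperature = effective_temperature,
                 move_probabilities = move_probabilities,
                 rng_seed = as.integer(rng_seed),
                 lambda_weight = lambda_weight,
                 report_stride = as.integer(report_stride),
                 n_best = as.integer(n_best), anneal_to = anneal_to),
            class = "mc_config")
}

## --- move implementations (draw from the current RNG stream) ---------

move_mutation <- function(pair, pattern, comp, table) {
  chain <- sample(c("A", "B"), 1)
  seq <- if (chain == "A") pair$seq_A else pair$seq_B
  chars <- seq_chars(seq)
  site <- sample(length(chars), 1)
  cls <- classify_residue(chars[site], table)
  pool <- switch(cls,
                 hydrophobic = table$hydrophobic,
                 polar = table$polar,
                 positive = table$positive,
                 negative = table$negative,
                 character(0))
  pool <- setdiff(pool, chars[site])
  if (!length(pool)) return(NULL)
  chars[site] <- sample(pool, 1)
  new_seq <- paste(chars, collapse = "")
  if (chain == "A") peptide_pair(new_seq, pair$seq_B)
  else peptide_pair(pair$seq_A, new_seq)
}

move_intra_exchange <- function(pair, pattern, comp, table) {
  chain <- sample(c("A", "B"), 1)
  seq <- if (chain == "A") pair$seq_A else pair$seq_B
  chars <- seq_chars(seq)
  ## swap two residues occupying sites of the same pattern class
  site_class <- sample(c("H", "P"), 1,
                       prob = c(length(pattern$h_sites),
                                length(pattern$p_sites)))
  sites <- if (site_class == "H") pattern$h_sites else pattern$p_sites
  if (length(sites) < 2) return(NULL)
  ij <- sample(sites, 2)
  if (chars[ij[1]] == chars[ij[2]]) return(NULL)
  chars[ij] <- chars[rev(ij)]
  new_seq <- paste(chars, collapse = "")
  if (chain == "A") peptide_pair(new_seq, pair$seq_B)
  else peptide_pair(pair$seq_A, new_seq)
}

move_inter_exchange <- function(pair, pattern, comp, table) {
  a <- seq_chars(pair$seq_A); b <- seq_chars(pair$seq_B)
  cls_a <- vapply(a, classify_residue, character(1), table = table)
  cls_b <- vapply(b, classify_residue, character(1), table = table)
  ## classes legal on both chains: hydrophobic<->hydrophobic or
  ## polar<->polar (charged residues are sign-specific per chain)
  cls <- sample(c("hydrophobic", "polar"), 1)
  ia <- which(cls_a == cls); ib <- which(cls_b == cls)
  if (!length(ia) || !length(ib)) return(NULL)
  i <- if (length(ia) == 1) ia else sample(ia, 1)
  j <- if (length(ib) == 1) ib else sample(ib, 1)
  if (a[i] == b[j]) return(NULL)
  tmp <- a[i]; a[i] <- b[j]; b[j] <- tmp
  peptide_pair(paste(a, collapse = ""), paste(b, collapse = ""))
}

#' Propose a constraint-preserving trial move
#'
#' Mutation replaces one residue by a different residue of the same class
#' (same charge sign on charged sites); intrachain exchange swaps two
#' residues occupying same-class sites of one chain; interchain exchange
#' swaps a hydrophobic or polar residue between the chains. The returned
#' pair always passes \code{\link{validate_pair}}.
#'
#' @param pair current \code{\link{peptide_pair}}.
#' @param move_type one of \code{"mutation"}, \code{"intra_exchange"},
#'   \code{"inter_exchange"}.
#' @param pattern,comp,table the sequence-space constraint objects.
#' @param max_retries bounded retries before failing on a degenerate
#'   alphabet.
#' @return a trial \code{peptide_pair}.
#' @export
propose_move <- function(pair, move_type, pattern = sequence_pattern(),
                         comp = composition_constraint(),
                         table = residue_classes(), max_retries = 100) {
  fn <- switch(move_type,
               mutation = move_mutation,
               intra_exchange = move_intra_exchange,
               inter_exchange = move_inter_exchange,
               stop("unknown move type: ", move_type))
  for (r in seq_len(max_retries)) {
    trial <- fn(pair, pattern, comp, table)
    if (!is.null(trial)) return(trial)
  }
  stop("no legal '", move_type, "' move found after ", max_retries,
       " retries (degenerate alphabet?)")
}

#' Metropolis acceptance test
#'
#' Score-lowering moves are always accepted; score-raising moves are
#' accepted with probability \code{exp(-delta/temperature)}.
#'
#' @param delta_gamma score change of the trial move (kcal/mol).
#' @param temperature effective temperature (kcal/mol, > 0).
#' @return logical.
#' @export
metropolis_accept <- function(delta_gamma, temperature) {
  stopifnot(temperature > 0)
  if (delta_gamma <= 0) return(TRUE)
  stats::runif(1) < exp(-delta_gamma / temperature)
}

#' Run the Monte Carlo sequence design
#'
#' Evolves a random initial pair under the design constraints, scoring
#' every trial on the fixed fibril scaffold, and returns the score trace,
#' the lowest-scoring distinct designs, and the final state. Fully
#' reproducible from \code{config$rng_seed}.
#'
#' @param config an \code{\link{mc_config}}.
#' @param pattern,comp,table sequence-space constraints.
#' @param scaffold fibril scaffold for the binding-energy term.
#' @param e_params,a_params energy and aggregation model parameters.
#' @return object of class \code{coapep_design} with components
#'   \code{trace} (data.frame: step, gamma, dg, p_agg, move_type,
#'   accepted), \code{best} (list of records with pair, score, step),
#'   \code{state} (final MC state) and \code{config}.
#' @examples
#' \donttest{
#' run <- design_pairs(mc_config(n_steps = 200, rng_seed = 1))
#' summary(run)
#' }
#' @export
design_pairs <- function(config = mc_config(),
                         pattern = sequence_pattern(),
                         comp = composition_constraint(),
                         table = residue_classes(),
                         scaffold = build_scaffold(),
                         e_params = energy_params(),
                         a_params = aggregation_params()) {
  set.seed(config$rng_seed)
  current <- random_pair(pattern, comp, table)
  current_score <- score_pair(current, scaffold, e_params, a_params,
                              config$lambda_weight)
  best <- list(list(pair = current, score = current_score, step = 0L))
  acc_counts <- c(mutation = 0L, intra_exchange = 0L, inter_exchange = 0L)
  try_counts <- acc_counts
  move_names <- names(config$move_probabilities)

  n_rec <- max(1L, config$n_steps %/% config$report_stride)
  trace <- data.frame(step = integer(n_rec), gamma = numeric(n_rec),
                      dg = numeric(n_rec), p_agg = numeric(n_rec),
                      move_type = character(n_rec),
                      accepted = logical(n_rec),
                      stringsAsFactors = FALSE)
  rec <- 0L
  temp_at <- function(step) {
    if (is.null(config$anneal_to)) return(config$effective_temperature)
    f <- (step - 1) / max(1, config$n_steps - 1)
    config$effective_temperature * (1 - f) + config$anneal_to * f
  }

  pair_key <- function(p) paste(p$seq_A, p$seq_B)
  best_keys <- pair_key(current)

  for (step in seq_len(config$n_steps)) {
    mv <- sample(move_names, 1, prob = config$move_probabilities)
    try_counts[mv] <- try_counts[mv] + 1L
    trial <- propose_move(current, mv, pattern, comp, table)
    trial_score <- score_pair(trial, scaffold, e_params, a_params,
                              config$lambda_weight)
    delta <- trial_score$gamma - current_score$gamma
    accepted <- metropolis_accept(delta, temp_at(step))
    if (accepted) {
      acc_counts[mv] <- acc_counts[mv] + 1L
      current <- trial
      current_score <- trial_score
      key <- pair_key(current)
      if (!key %in% best_keys) {
        best <- c(best, list(list(pair = current, score = current_score,
                                  step = step)))
        best_keys <- c(best_keys, key)
        ord <- order(vapply(best, function(b) b$score$gamma, numeric(1)))
        keep <- ord[seq_len(min(length(best), config$n_best))]
        best <- best[keep]
        best_keys <- best_keys[keep]
      }
    }
    if (step %% config$report_stride == 0L) {
      rec <- rec + 1L
      trace$step[rec] <- step
      trace$gamma[rec] <- current_score$gamma
      trace$dg[rec] <- current_score$dg_binding
      trace$p_agg[rec] <- current_score$p_agg
      trace$move_type[rec] <- mv
      trace$accepted[rec] <- accepted
    }
  }
  trace <- trace[seq_len(rec), , drop = FALSE]
  ord <- order(vapply(best, function(b) b$score$gamma, numeric(1)))
  best <- best[ord]
  state <- list(current_pair = current, current_score = current_score,
                best_pair = best[[1]]$pair, best_score = best[[1]]$score,
                step_index = config$n_steps,
                acceptance_counts = acc_counts,
                proposal_counts = try_counts)
  structure(list(trace = trace, best = best, state = state,
                 config = config),
            class = "coapep_design")
}

#' @export
print.coapep_design <- function(x, ...) {
  cat(sprintf("MC sequence design: %d steps, lambda = %.1f, T = %.2f, seed %d\n",
              x$config$n_steps, x$config$lambda_weight,
              x$config$effective_temperature, x$config$rng_seed))
  b <- x$best[[1]]
  cat(sprintf("Best design (step %d, gamma = %.3f kcal/mol):\n",
              b$step, b$score$gamma))
  cat("  A (+):", b$pair$seq_A, "\n  B (-):", b$pair$seq_B, "\n")
  invisible(x)
}

#' @export
summary.coapep_design <- function(object, ...) {
  acc <- object$state$acceptance_counts
  tries <- object$state$proposal_counts
  rate <- ifelse(tries > 0, acc / tries, NA_real_)
  best_tab <- do.call(rbind, lapply(object$best, function(b) {
    data.frame(seq_A = b$pair$seq_A, seq_B = b$pair$seq_B,
               gamma = b$score$gamma, dg = b$score$dg_binding,
               p_agg = b$score$p_agg, step = b$step,
               stringsAsFactors = FALSE)
  }))
  out <- list(config = object$config, best = best_tab,
              acceptance_rate = rate,
              final_gamma = object$state$current_score$gamma)
  class(out) <- "summary.coapep_design"
  out
}

#' @export
print.summary.coapep_design <- function(x, ...) {
  cat(sprintf("MC design run (%d steps, lambda = %.1f)\n",
              x$config$n_steps, x$config$lambda_weight))
  cat("Acceptance rates by move:\n")
  for (nm in names(x$acceptance_rate)) {
    cat(sprintf("  %-15s %.3f\n", nm, x$acceptance_rate[nm]))
  }
  cat("Best designs:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}

#' @export
coef.coapep_design <- function(object, ...) {
  coef(object$best[[1]]$score)
}

#' Plot the score trace of a design run
#'
#' @param x a \code{coapep_design} object.
#' @param ... passed to \code{plot.default}.
#' @export
plot.coapep_design <- function(x, ...) {
  graphics::plot(x$trace$step, x$trace$gamma, type = "l",
                 xlab = "evolution step", ylab = "score (kcal/mol)", ...)
  b <- x$best[[1]]
  graphics::points(b$step, b$score$gamma, col = "red", pch = 1, cex = 2)
  invisible(x)
}

#' Write a score trace as CSV
#'
#' @param run a \code{coapep_design} object.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(run, path) {
  utils::write.csv(run$trace, path, row.names = FALSE)
  invisible(path)
}
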