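## Analysis of multi-chain assembly frames (Calpha traces): strand
## orientation, sheet partitioning, nearest-neighbor identity statistics,
## A:B composition among aggregated chains, and beta-sheet content over a
## trajectory. All statistics are distance-based, hence invariant under
## rigid motions and chain relabeling.

#' Construct an assembly frame
#'
#' @param chains list of chains, each a list with \code{id} (character),
#'   \code{species} (\code{"A"}, \code{"B"} or \code{"unknown"}) and
#'   \code{ca} (n x 3 numeric matrix of Calpha coordinates, Angstrom).
#' @param time_stamp frame time (arbitrary units).
#' @return object of class \code{assembly_frame}.
#' @export
assembly_frame <- function(chains, time_stamp = 0) {
  n_res <- unique(vapply(chains, function(ch) nrow(ch$ca), integer(1)))
  if (length(n_res) != 1L) {
    stop("all chains must have the same residue count")
  }
  for (ch in chains) {
    if (!all(is.finite(ch$ca))) stop("non-finite coordinates in chain ",
                                     ch$id)
  }
  structure(list(chains = chains, time_stamp = time_stamp,
                 n_residues = n_res),
            class = "assembly_frame")
}

#' @export
print.assembly_frame <- function(x, ...) {
  sp <- vapply(x$chains, function(ch) ch$species, character(1))
  cat(sprintf("Assembly frame: %d chains x %d residues (t = %s)\n",
              length(x$chains), x$n_residues, format(x$time_stamp)))
  cat("  species counts:", paste(names(table(sp)), table(sp),
                                 sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert a built scaffold into an assembly frame
#'
#' @param scaffold a \code{fibril_scaffold}.
#' @param time_stamp frame time.
#' @return an \code{\link{assembly_frame}} carrying the scaffold's slot
#'   species labels.
#' @export
scaffold_to_frame <- function(scaffold, time_stamp = 0) {
  chains <- lapply(seq_len(nrow(scaffold$slots)), function(k) {
    list(id = scaffold$slots$chain_id[k],
         species = scaffold$slots$species[k],
         ca = scaffold$ca[[k]])
  })
  assembly_frame(chains, time_stamp)
}

#' Signed principal-axis unit vector of a strand
#'
#' The first principal axis of the Calpha set, with sign fixed so the
#' vector points from the N to the C terminus.
#'
#' @param ca n x 3 matrix of Calpha coordinates (n >= 2).
#' @return unit 3-vector.
#' @export
strand_vector <- function(ca) {
  stopifnot(nrow(ca) >= 2)
  centered <- sweep(ca, 2, colMeans(ca))
  if (max(abs(centered)) < 1e-12) {
    stop("degenerate strand: all Calpha coincide")
  }
  v <- svd(centered, nu = 0, nv = 1)$v[, 1]
  nc <- ca[nrow(ca), ] - ca[1, ]
  if (sum(v * nc) < 0) v <- -v
  v / sqrt(sum(v^2))
}

#' Classify the relative orientation of two strand vectors
#'
#' @param v1,v2 unit vectors.
#' @param cos_threshold classification threshold on the dot product.
#' @return \code{"parallel"}, \code{"antiparallel"} or
#'   \code{"unclassified"}.
#' @export
classify_pair_orientation <- function(v1, v2, cos_threshold = 0.5) {
  d <- sum(v1 * v2)
  if (d >= cos_threshold) "parallel"
  else if (d <= -cos_threshold) "antiparallel"
  else "unclassified"
}

## Mean aligned Calpha-Calpha distance between two chains, minimized over
## direct and reversed residue pairing (register-insensitive to direction).
registry_distance <- function(ca_i, ca_j) {
  direct <- mean(sqrt(rowSums((ca_i - ca_j)^2)))
  rev_j <- ca_j[rev(seq_len(nrow(ca_j))), , drop = FALSE]
  reversed <- mean(sqrt(rowSums((ca_i - rev_j)^2)))
  min(direct, reversed)
}

## Number of aligned Calpha pairs within the registry cutoff (max over
## direct and reversed pairing).
aligned_pair_count <- function(ca_i, ca_j, cutoff) {
  direct <- sum(sqrt(rowSums((ca_i - ca_j)^2)) < cutoff)
  rev_j <- ca_j[rev(seq_len(nrow(ca_j))), , drop = FALSE]
  reversed <- sum(sqrt(rowSums((ca_i - rev_j)^2)) < cutoff)
  max(direct, reversed)
}

registry_distance_matrix <- function(frame) {
  n <- length(frame$chains)
  d <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) {
        d[i, j] <- d[j, i] <- registry_distance(frame$chains[[i]]$ca,
                                                frame$chains[[j]]$ca)
      }
    }
  }
  diag(d) <- 0
  d
}

#' Partition the chains of a frame into beta sheets
#'
#' Chains are linked when their mean aligned Calpha distance falls below
#' the in-sheet cutoff; connected components are sheets. Isolated chains
#' form singleton sheets. Sheet ids are ordered by lowest member chain
#' index.
#'
#' @param frame an \code{\link{assembly_frame}}.
#' @param in_sheet_cutoff linkage cutoff (Angstrom, default 5.5).
#' @return integer vector of sheet ids, one per chain.
#' @export
partition_sheets <- function(frame, in_sheet_cutoff = 5.5) {
  n <- length(frame$chains)
  d <- registry_distance_matrix(frame)
  adj <- d < in_sheet_cutoff
  diag(adj) <- FALSE
  comp <- integer(n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

species_pair_label <- function(s1, s2) {
  paste(sort(c(s1, s2)), collapse = "")
}

tally_pairs <- function(frame, pairs, vecs, cos_threshold) {
  if (!nrow(pairs)) {
    return(data.frame(species_pair = character(0),
                      orientation = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  lab <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    sp <- species_pair_label(frame$chains[[i]]$species,
                             frame$chains[[j]]$species)
    ori <- classify_pair_orientation(vecs[[i]], vecs[[j]], cos_threshold)
    paste(sp, ori, sep = ":")
  }, character(1))
  tab <- table(lab)
  parts <- strsplit(names(tab), ":", fixed = TRUE)
  data.frame(species_pair = vapply(parts, `[`, character(1), 1),
             orientation = vapply(parts, `[`, character(1), 2),
             count = as.integer(tab), stringsAsFactors = FALSE)
}

## Unique unordered pairs from a 2-column index matrix.
dedupe_pairs <- function(m) {
  if (!nrow(m)) return(m)
  key <- paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  m[!duplicated(key), , drop = FALSE]
}

#' Neighbor identity and orientation statistics
#'
#' For every chain, finds its nearest and next-nearest same-sheet
#' neighbors and its nearest chain on any other sheet (by mean aligned
#' Calpha distance), classifies each pair's species identity and relative
#' orientation, and tallies the counts. Symmetric pairs are counted once.
#'
#' @param frame an \code{\link{assembly_frame}}.
#' @param partition sheet assignment from \code{\link{partition_sheets}}.
#' @param cos_threshold orientation classification threshold.
#' @param shell_tol distance-shell tolerance (Angstrom): the next-nearest
#'   neighbor is the closest chain more than \code{shell_tol} farther than
#'   the nearest one, so the two flanking strands of an interior strand
#'   (equidistant up to noise) both count as nearest.
#' @return object of class \code{orientation_stats} with tallies
#'   \code{within_nearest}, \code{within_next_nearest},
#'   \code{cross_nearest} and a \code{totals} vector.
#' @export
neighbor_statistics <- function(frame, partition = partition_sheets(frame),
                                cos_threshold = 0.5, shell_tol = 1.0) {
  n <- length(frame$chains)
  d <- registry_distance_matrix(frame)
  vecs <- lapply(frame$chains, function(ch) strand_vector(ch$ca))
  near <- NULL; nextn <- NULL; cross <- NULL
  for (i in seq_len(n)) {
    same <- which(partition == partition[i] & seq_len(n) != i)
    if (length(same)) {
      ord <- same[order(d[i, same])]
      near <- rbind(near, c(i, ord[1]))
      d_near <- d[i, ord[1]]
      shell2 <- ord[d[i, ord] > d_near + shell_tol]
      if (length(shell2)) nextn <- rbind(nextn, c(i, shell2[1]))
    }
    other <- which(partition != partition[i])
    if (length(other)) {
      cross <- rbind(cross, c(i, other[which.min(d[i, other])]))
    }
  }
  empty <- matrix(integer(0), ncol = 2)
  near <- dedupe_pairs(if (is.null(near)) empty else near)
  nextn <- dedupe_pairs(if (is.null(nextn)) empty else nextn)
  cross <- dedupe_pairs(if (is.null(cross)) empty else cross)
  out <- list(within_nearest = tally_pairs(frame, near, vecs,
                                           cos_threshold),
              within_next_nearest = tally_pairs(frame, nextn, vecs,
                                                cos_threshold),
              cross_nearest = tally_pairs(frame, cross, vecs,
                                          cos_threshold))
  out$totals <- c(within_nearest = nrow(near),
                  within_next_nearest = nrow(nextn),
                  cross_nearest = nrow(cross))
  class(out) <- "orientation_stats"
  out
}

#' @export
print.orientation_stats <- function(x, ...) {
  cat("Neighbor statistics (pairs counted once):\n")
  for (nm in c("within_nearest", "within_next_nearest", "cross_nearest")) {
    cat(" ", nm, ":\n", sep = "")
    if (nrow(x[[nm]])) {
      print(x[[nm]], row.names = FALSE)
    } else cat("   (none)\n")
  }
  invisible(x)
}

#' A:B composition ratio among aggregated chains
#'
#' An aggregated chain is a member of a sheet of size >= 2. The ratio is
#' (number of aggregated A chains) / (number of aggregated B chains);
#' undefined (NA, with a warning) when no aggregated B chain exists.
#'
#' @param frame an \code{\link{assembly_frame}}.
#' @param partition optional precomputed sheet assignment.
#' @param in_sheet_cutoff passed to \code{\link{partition_sheets}}.
#' @return numeric ratio (or NA).
#' @export
composition_ratio <- function(frame, partition = NULL,
                              in_sheet_cutoff = 5.5) {
  if (is.null(partition)) {
    partition <- partition_sheets(frame, in_sheet_cutoff)
  }
  size <- table(partition)
  agg <- partition %in% as.integer(names(size)[size >= 2])
  sp <- vapply(frame$chains, function(ch) ch$species, character(1))
  n_a <- sum(agg & sp == "A")
  n_b <- sum(agg & sp == "B")
  if (n_b == 0) {
    warning("no aggregated B chains: composition ratio undefined")
    return(NA_real_)
  }
  n_a / n_b
}

#' Beta-sheet content of a trajectory
#'
#' A peptide counts as in-sheet when it has at least one neighbor with at
#' least \code{min_aligned} aligned Calpha pairs within the registry
#' cutoff. Returns the in-sheet fraction per frame.
#'
#' @param frames a list of \code{\link{assembly_frame}} objects (or a
#'   single frame).
#' @param registry_cutoff per-residue alignment cutoff (Angstrom).
#' @param min_aligned minimum aligned Calpha pairs (default 4).
#' @return data.frame of class \code{beta_content_series} with columns
#'   \code{time} and \code{beta_fraction} (values in [0, 1]).
#' @export
beta_content <- function(frames, registry_cutoff = 6.0, min_aligned = 4) {
  if (inherits(frames, "assembly_frame")) frames <- list(frames)
  stopifnot(length(frames) >= 1)
  rows <- lapply(frames, function(fr) {
    n <- length(fr$chains)
    in_sheet <- logical(n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j || in_sheet[i]) next
        if (aligned_pair_count(fr$chains[[i]]$ca, fr$chains[[j]]$ca,
                               registry_cutoff) >= min_aligned) {
          in_sheet[i] <- TRUE
        }
      }
    }
    data.frame(time = fr$time_stamp, beta_fraction = mean(in_sheet))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("beta_content_series", "data.frame")
  out
}

#' Read a PDB file as assembly frames
#'
#' Multi-model PDB files are treated as trajectory frames; each chain's
#' Calpha trace is extracted in residue order. Species labels come from an
#' explicit chain-id map, or are inferred by matching each chain's
#' sequence to the supplied pair; with neither, a chain with net positive
#' side-chain charge is labeled \code{"A"}, net negative \code{"B"}, and
#' neutral \code{"unknown"}.
#'
#' @param path PDB file path.
#' @param species_map optional named character vector mapping chain ids to
#'   \code{"A"}/\code{"B"}.
#' @param pair optional \code{\link{peptide_pair}} for sequence-based
#'   species inference.
#' @return list of \code{\link{assembly_frame}} objects.
#' @export
read_assembly_pdb <- function(path, species_map = NULL, pair = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  ca_sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
  atoms <- pdb$atom[ca_sel$atom, , drop = FALSE]
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  aa1 <- stats::setNames(names(AA3), AA3)
  lapply(seq_len(n_models), function(m) {
    coords <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)[ca_sel$atom, ,
                                                       drop = FALSE]
    chains <- lapply(unique(atoms$chain), function(cid) {
      sel <- atoms$chain == cid
      ord <- order(atoms$resno[sel])
      seq1 <- paste(aa1[atoms$resid[sel][ord]], collapse = "")
      species <- "unknown"
      if (!is.null(species_map) && cid %in% names(species_map)) {
        species <- species_map[[cid]]
      } else if (!is.null(pair)) {
        if (seq1 == pair$seq_A) species <- "A"
        else if (seq1 == pair$seq_B) species <- "B"
      } else {
        q <- sum(RESIDUE_CHARGE[strsplit(seq1, "")[[1]]], na.rm = TRUE)
        if (q > 0) species <- "A" else if (q < 0) species <- "B"
      }
      list(id = cid, species = species, sequence = seq1,
           ca = coords[sel, , drop = FALSE][ord, , drop = FALSE])
    })
    assembly_frame(chains, time_stamp = m - 1)
  })
}
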