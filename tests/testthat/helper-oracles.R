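# Independent oracles and small fixture builders used across tests.
# The binding-energy oracle is a deliberately plain all-pairs double loop,
# written separately from the vectorized production path.

oracle_charge <- c(K = 1, R = 1, D = -1, E = -1)

oracle_eps_class <- function(aa, dielectrics) {
  if (aa %in% names(oracle_charge)) return(dielectrics[["charged"]])
  if (aa %in% c("S", "T", "N", "Q", "Y", "H", "W")) {
    return(dielectrics[["polar"]])
  }
  dielectrics[["nonpolar"]]
}

oracle_binding_energy <- function(pair, scaffold, params) {
  n_res <- scaffold$geometry$n_residues
  res <- lapply(scaffold$slots$species, function(sp) {
    strsplit(if (sp == "A") pair$seq_A else pair$seq_B, "")[[1]]
  })
  cent <- lapply(seq_along(scaffold$ca), function(k) {
    scaffold$ca[[k]] +
      scaffold$sc_dir[[k]] * params$sidechain_extent[res[[k]]]
  })
  e_h <- params$hbond_energy * sum(scaffold$hbond_registry$n_hbonds)
  e_c <- 0
  e_e <- 0
  n <- nrow(scaffold$slots)
  for (k1 in seq_len(n - 1)) {
    for (k2 in (k1 + 1):n) {
      for (i in seq_len(n_res)) {
        for (j in seq_len(n_res)) {
          r <- sqrt(sum((cent[[k1]][i, ] - cent[[k2]][j, ])^2))
          a1 <- res[[k1]][i]
          a2 <- res[[k2]][j]
          if (r <= params$contact_cutoff) {
            e_c <- e_c + params$contact_table[a1, a2]
          }
          q1 <- if (a1 %in% names(oracle_charge)) oracle_charge[[a1]] else 0
          q2 <- if (a2 %in% names(oracle_charge)) oracle_charge[[a2]] else 0
          if (q1 != 0 && q2 != 0) {
            eps <- max(oracle_eps_class(a1, params$dielectric_by_class),
                       oracle_eps_class(a2, params$dielectric_by_class))
            e_e <- e_e + params$coulomb_constant * q1 * q2 / (eps * r)
          }
        }
      }
    }
  }
  # desolvation: charged centroids strictly inside the inter-sheet slab
  e_d <- 0
  sheets <- scaffold$slots$sheet
  if (length(unique(sheets)) >= 2) {
    us <- sort(unique(sheets))
    c1 <- colMeans(do.call(rbind, scaffold$ca[sheets == us[1]]))
    c2 <- colMeans(do.call(rbind, scaffold$ca[sheets == us[2]]))
    ax <- (c2 - c1) / sqrt(sum((c2 - c1)^2))
    lo <- sum(c1 * ax) + params$burial_margin
    hi <- sum(c2 * ax) - params$burial_margin
    n_b <- 0
    for (k in seq_len(n)) {
      for (i in seq_len(n_res)) {
        if (res[[k]][i] %in% names(oracle_charge)) {
          pr <- sum(cent[[k]][i, ] * ax)
          if (pr > lo && pr < hi) n_b <- n_b + 1
        }
      }
    }
    e_d <- params$desolvation_penalty * n_b
  }
  (e_h + e_c + e_e + e_d) / n
}

# Random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_dec)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Permute the slot order of a scaffold (relabeling invariance fixture).
permute_scaffold <- function(scaffold, perm) {
  inv <- order(perm)
  scaffold$slots <- scaffold$slots[perm, , drop = FALSE]
  scaffold$ca <- scaffold$ca[perm]
  scaffold$sc_dir <- scaffold$sc_dir[perm]
  scaffold$hbond_registry$slot_i <- inv[scaffold$hbond_registry$slot_i]
  scaffold$hbond_registry$slot_j <- inv[scaffold$hbond_registry$slot_j]
  scaffold
}

# Gaussian-noise copy of an assembly frame.
noisy_frame <- function(frame, sd) {
  frame$chains <- lapply(frame$chains, function(ch) {
    ch$ca <- ch$ca + matrix(rnorm(length(ch$ca), 0, sd), ncol = 3)
    ch
  })
  frame
}

# Brute-force enumeration of the admissible single-chain space for toy
# alphabets: generate every string over the union alphabet and count the
# ones passing the site-class/composition/charge rules.
brute_force_chain_count <- function(pattern, comp, table, chain) {
  chars <- strsplit(pattern$pattern, "")[[1]]
  pool <- c(table$hydrophobic, table$polar,
            if (chain == "A") table$positive else table$negative)
  grids <- rep(list(pool), length(chars))
  all_seq <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
  n_ok <- 0
  for (r in seq_len(nrow(all_seq))) {
    s <- unlist(all_seq[r, ], use.names = FALSE)
    ok <- TRUE
    n_h <- 0; n_p <- 0; n_c <- 0; q <- 0
    for (i in seq_along(s)) {
      cls <- if (s[i] %in% table$hydrophobic) "h"
      else if (s[i] %in% table$polar) "p"
      else if (s[i] %in% table$positive) "pos"
      else if (s[i] %in% table$negative) "neg"
      else "x"
      if (chars[i] == "H" && cls != "h") ok <- FALSE
      if (chars[i] == "P" && !(cls %in% c("p", "pos", "neg"))) ok <- FALSE
      if (cls == "pos" && chain != "A") ok <- FALSE
      if (cls == "neg" && chain != "B") ok <- FALSE
      n_h <- n_h + (cls == "h"); n_p <- n_p + (cls == "p")
      n_c <- n_c + (cls %in% c("pos", "neg"))
      q <- q + (cls == "pos") - (cls == "neg")
    }
    want_q <- if (chain == "A") comp$charge_A else comp$charge_B
    if (ok && n_h == comp$n_hydrophobic && n_p == comp$n_polar &&
        n_c == comp$n_charged && q == want_q) {
      n_ok <- n_ok + 1
    }
  }
  n_ok
}
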