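# Independent oracles used to cross-check the package's recursive estimators.
# These deliberately use brute-force enumeration rather than the recursions
# they are checking.

# Equivalent complete generations by explicit enumeration of every ancestor
# path: each occurrence of a known ancestor at depth g contributes (1/2)^g.
ge_path_enumeration <- function(ped, i) {
  par <- studbook:::ped_parents(ped)
  total <- 0
  stack <- list(c(i, 0))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (p in c(par$sire[top[1]], par$dam[top[1]])) {
      if (p > 0L) {
        total <- total + 0.5^(top[2] + 1)
        stack[[length(stack) + 1L]] <- c(p, top[2] + 1)
      }
    }
  }
  total
}

# Exact founder-allele retention by enumerating all Mendelian transmission
# outcomes (2 per known parent link). Only feasible for toy pedigrees
# (<= ~14 meioses).
gene_drop_enumeration <- function(ped, reference) {
  par <- studbook:::ped_parents(ped)
  n <- nrow(ped)
  fo <- is.na(ped$sire) & is.na(ped$dam)
  frank <- cumsum(fo)
  ref <- match(reference, ped$id)
  stopifnot(!anyNA(ref))

  links <- data.frame(animal = integer(0), side = character(0))
  for (i in which(!fo)) {
    if (par$sire[i] > 0L) links <- rbind(links, data.frame(animal = i, side = "s"))
    if (par$dam[i] > 0L) links <- rbind(links, data.frame(animal = i, side = "d"))
  }
  m <- nrow(links)
  stopifnot(m <= 14)

  founders <- which(fo)
  r_sum <- numeric(length(founders))
  for (combo in 0:(2^m - 1)) {
    pick <- as.integer(intToBits(combo))[seq_len(max(m, 1))]
    a1 <- integer(n); a2 <- integer(n)
    for (i in seq_len(n)) {
      if (fo[i]) { a1[i] <- 2L * frank[i] - 1L; a2[i] <- 2L * frank[i]; next }
      s <- par$sire[i]; d <- par$dam[i]
      if (s > 0L) {
        k <- which(links$animal == i & links$side == "s")
        a1[i] <- if (pick[k] == 0L) a1[s] else a2[s]
      } else a1[i] <- -(2L * i - 1L)
      if (d > 0L) {
        k <- which(links$animal == i & links$side == "d")
        a2[i] <- if (pick[k] == 0L) a1[d] else a2[d]
      } else a2[i] <- -(2L * i)
    }
    present <- unique(c(a1[ref], a2[ref]))
    for (fi in seq_along(founders)) {
      k <- frank[founders[fi]]
      r_sum[fi] <- r_sum[fi] +
        (as.integer((2L * k - 1L) %in% present) + as.integer((2L * k) %in% present)) / 2
    }
  }
  stats::setNames(r_sum / 2^m, ped$id[founders])
}

# small random studbook-like pedigree for property tests
random_pedigree <- function(seed, n_founders = 30, n_years = 6,
                            offspring_per_year = 45,
                            missing_parent_rate = 0.1,
                            n_active_sires = 5, n_breeds = 2,
                            reference_fraction = 0.4) {
  simulate_pedigree(sim_config(
    n_founders = n_founders, founder_sex_ratio = 0.4, n_years = n_years,
    offspring_per_year = offspring_per_year, n_active_sires = n_active_sires,
    sire_concentration = 0.5, missing_parent_rate = missing_parent_rate,
    n_breeds = n_breeds, reference_fraction = reference_fraction, seed = seed))
}
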