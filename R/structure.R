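#' Resolve a subset selector to row indices
#'
#' Selectors used throughout the package: `"reference"` (animals flagged
#' `in_reference`), `"all"`, a logical vector, an integer index vector, or a
#' character vector of animal ids.
#' @keywords internal
resolve_subset <- function(ped, subset) {
  if (is.null(subset)) return(seq_len(nrow(ped)))
  if (is.character(subset) && length(subset) == 1L && subset %in% c("reference", "all")) {
    return(if (subset == "all") seq_len(nrow(ped)) else which(ped$in_reference))
  }
  if (is.logical(subset)) {
    stopifnot(length(subset) == nrow(ped))
    return(which(subset))
  }
  if (is.numeric(subset)) return(as.integer(subset))
  idx <- match(subset, ped$id)
  if (anyNA(idx)) stop("unknown animal id(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  idx
}

#' Longest ancestral path per animal
#'
#' Generations back to the most remote known ancestor: 0 for founders,
#' otherwise 1 + the maximum over known parents.
#'
#' @param ped a `pedigree` (topologically ordered).
#' @return integer vector aligned with `ped` rows.
#' @export
ancestral_path_length <- function(ped) {
  par <- ped_parents(ped)
  n <- nrow(ped)
  g <- integer(n)
  for (i in seq_len(n)) {
    ps <- c(par$sire[i], par$dam[i])
    ps <- ps[ps > 0L]
    g[i] <- if (length(ps)) 1L + max(g[ps]) else 0L
  }
  g
}

#' Pedigree structure counts
#'
#' Tallies the classic studbook structure table: totals by sex, founders
#' (both parents unknown), non-founders, non-founders with both parents
#' known, animals with and without offspring, full-sib groups (matings of a
#' known sire-dam pair with at least two offspring), the longest ancestral
#' path (LAP) in the whole pedigree, and the mean of per-animal longest
#' ancestral paths over `reference`.
#'
#' @param ped a `pedigree`.
#' @param reference subset selector for `mean_max_generations`
#'   (default `"all"`; see [resolve_subset()]).
#' @return list of class `structure_report`.
#' @export
count_structure <- function(ped, reference = "all") {
  stopifnot(inherits(ped, "pedigree"))
  if (nrow(ped) == 0L) stop("empty pedigree")
  ref <- resolve_subset(ped, reference)
  fo <- is_founder(ped)
  both <- !is.na(ped$sire) & !is.na(ped$dam)
  has_off <- ped$id %in% c(ped$sire, ped$dam)
  g <- ancestral_path_length(ped)

  pair <- paste(ped$sire, ped$dam)[both]
  fullsib <- sum(table(pair) >= 2L)

  by_sex <- function(x) c(male = sum(x & ped$sex == "M"),
                          female = sum(x & ped$sex == "F"),
                          total = sum(x))
  out <- list(
    n_total = nrow(ped),
    n_male = sum(ped$sex == "M"),
    n_female = sum(ped$sex == "F"),
    n_founders = sum(fo),
    n_nonfounders = sum(!fo),
    n_nonfounders_both_known = sum(both),
    n_with_offspring = sum(has_off),
    n_without_offspring = sum(!has_off),
    n_fullsib_groups = fullsib,
    LAP = max(g),
    mean_max_generations = mean(g[ref]),
    by_sex = rbind(
      founders = by_sex(fo),
      nonfounders = by_sex(!fo),
      nonfounders_both_known = by_sex(both),
      with_offspring = by_sex(has_off),
      without_offspring = by_sex(!has_off)
    )
  )
  class(out) <- "structure_report"
  out
}

#' @export
print.structure_report <- function(x, ...) {
  cat(sprintf(
    paste0("Pedigree structure\n  animals: %d (%d male / %d female)\n",
           "  founders: %d   non-founders: %d (both parents known: %d)\n",
           "  full-sib groups: %d   LAP: %d generations",
           "   mean max generations: %.2f\n"),
    x$n_total, x$n_male, x$n_female, x$n_founders, x$n_nonfounders,
    x$n_nonfounders_both_known, x$n_fullsib_groups, x$LAP,
    x$mean_max_generations))
  invisible(x)
}

#' Equivalent complete generations
#'
#' Pedigree depth of each animal as the sum over every known-ancestor path
#' of (1/2)^generation, computed with the recursion
#' `g_e(i) = sum over known parents p of (1 + g_e(p)) / 2`. An ancestor
#' reachable along k distinct paths contributes each path's term. Equals the
#' number of fully known generations when the pedigree is complete to that
#' depth.
#'
#' @param ped a `pedigree`.
#' @param individuals subset selector (default `"reference"` if any animal is
#'   flagged, otherwise `"all"`).
#' @return list with `g_e` (named per-individual values), and summary
#'   `mean`, `min`, `max` over the subset.
#' @export
equivalent_generations <- function(ped, individuals = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(individuals)) {
    individuals <- if (any(ped$in_reference)) "reference" else "all"
  }
  idx <- resolve_subset(ped, individuals)
  par <- ped_parents(ped)
  n <- nrow(ped)
  ge <- numeric(n)
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    ge[i] <- (if (s > 0L) (1 + ge[s]) / 2 else 0) +
      (if (d > 0L) (1 + ge[d]) / 2 else 0)
  }
  vals <- stats::setNames(ge[idx], ped$id[idx])
  list(g_e = vals, mean = mean(vals), min = min(vals), max = max(vals))
}

#' Pedigree completeness index
#'
#' Fraction of ancestor slots filled with known animals over the first
#' `depth` generations: `c_p = a_k / sum_{i=1..depth} 2^i`, where an ancestor
#' occupying several slots counts once per slot. The conventional depth is 5
#' (62 slots).
#'
#' @param ped a `pedigree`.
#' @param individuals subset selector (defaults like
#'   [equivalent_generations()]).
#' @param depth number of ancestor generations to score (>= 1).
#' @return list with per-individual `c_p`, per-individual known-slot counts
#'   `a_k`, the slot total `n_slots`, and the subset `mean`.
#' @export
pedigree_completeness <- function(ped, individuals = NULL, depth = 5L) {
  stopifnot(inherits(ped, "pedigree"), depth >= 1L)
  if (is.null(individuals)) {
    individuals <- if (any(ped$in_reference)) "reference" else "all"
  }
  idx <- resolve_subset(ped, individuals)
  par <- ped_parents(ped)
  n <- nrow(ped)
  # known[i, d]: number of known ancestors of i at exactly generation d
  known <- matrix(0, n, depth)
  for (i in seq_len(n)) {
    ps <- c(par$sire[i], par$dam[i])
    ps <- ps[ps > 0L]
    known[i, 1L] <- length(ps)
    if (depth > 1L && length(ps)) {
      for (p in ps) known[i, 2:depth] <- known[i, 2:depth] + known[p, 1:(depth - 1L)]
    }
  }
  a_k <- rowSums(known)[idx]
  n_slots <- sum(2^(seq_len(depth)))
  c_p <- a_k / n_slots
  list(c_p = stats::setNames(c_p, ped$id[idx]),
       a_k = stats::setNames(a_k, ped$id[idx]),
       n_slots = n_slots, mean = mean(c_p))
}

#' Generation intervals along the four parent-offspring paths
#'
#' Average age of parents at the birth of their offspring, split into the
#' four classic paths (father-son, father-daughter, mother-son,
#' mother-daughter). The default mode restricts to offspring that themselves
#' reproduced (the classical generation-interval definition); mode
#' `"all_offspring"` uses every parent-offspring pair. Pairs missing either
#' birth year are dropped and counted.
#'
#' @param ped a `pedigree`.
#' @param mode `"reproducing_offspring"` or `"all_offspring"`.
#' @return list of class `generation_intervals` with a per-path `table`
#'   (N, mean, sd, se), the pair-count-weighted `pooled` row, the unweighted
#'   four-path mean, and the number of pairs dropped for missing years.
#' @export
generation_intervals <- function(ped,
                                 mode = c("reproducing_offspring", "all_offspring")) {
  stopifnot(inherits(ped, "pedigree"))
  mode <- match.arg(mode)
  par <- ped_parents(ped)
  n <- nrow(ped)
  keep <- if (mode == "reproducing_offspring") {
    ped$id %in% c(ped$sire, ped$dam)
  } else rep(TRUE, n)

  rows <- list()
  dropped <- 0L
  for (side in c("sire", "dam")) {
    p <- par[[side]]
    off <- which(p > 0L & keep)
    if (!length(off)) next
    iv <- ped$birth_year[off] - ped$birth_year[p[off]]
    bad <- is.na(iv)
    dropped <- dropped + sum(bad)
    off <- off[!bad]; iv <- iv[!bad]
    for (osex in c("M", "F")) {
      sel <- ped$sex[off] == osex
      path <- paste0(if (side == "sire") "father" else "mother", "-",
                     if (osex == "M") "son" else "daughter")
      rows[[path]] <- data.frame(path = path, N = sum(sel),
                                 mean = mean(iv[sel]), sd = stats::sd(iv[sel]),
                                 stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no usable parent-offspring pairs with birth years")
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab$se <- tab$sd / sqrt(tab$N)
  pooled <- pool_interval_paths(tab$N, tab$mean, tab$sd)
  out <- list(table = tab, pooled = pooled,
              unweighted_four_path_mean = mean(tab$mean[tab$N > 0]),
              n_dropped_missing_year = dropped, mode = mode)
  class(out) <- "generation_intervals"
  out
}

#' Pool per-path generation-interval statistics
#'
#' Combines path rows (pair counts, means, SDs) into the pooled total row:
#' the pooled mean is the pair-count-weighted mean of the path means, the
#' pooled SD pools within- and between-path variation, and SE = SD/sqrt(N).
#'
#' @param N pair counts per path.
#' @param mean mean interval (years) per path.
#' @param sd optional SD per path (needed for the pooled SD).
#' @return one-row data frame with `N`, `mean`, `sd`, `se`.
#' @export
pool_interval_paths <- function(N, mean, sd = NULL) {
  stopifnot(length(N) == length(mean), all(N >= 0))
  keep <- N > 0
  N <- N[keep]; mean <- mean[keep]
  Ntot <- sum(N)
  m <- sum(N * mean) / Ntot
  s <- NA_real_
  if (!is.null(sd)) {
    sd <- sd[keep]
    ss <- sum((N - 1) * sd^2, na.rm = TRUE) + sum(N * (mean - m)^2)
    s <- sqrt(ss / (Ntot - 1))
  }
  data.frame(N = Ntot, mean = m, sd = s, se = s / sqrt(Ntot))
}

#' @export
print.generation_intervals <- function(x, ...) {
  cat("Generation intervals (", x$mode, ")\n", sep = "")
  tab <- rbind(x$table,
               data.frame(path = "total", x$pooled))
  print(format(tab, digits = 4), row.names = FALSE)
  cat(sprintf("unweighted four-path mean: %.4f years\n",
              x$unweighted_four_path_mean))
  invisible(x)
}
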