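#' Configuration for the synthetic studbook generator
#'
#' The generator emulates the structure of a warmblood sport-horse studbook:
#' a founder population of unknown-parent animals, overlapping birth-year
#' cohorts, a small pool of heavily used (polygamous) sires whose use is
#' deliberately unequal, dams producing in consecutive seasons, incomplete
#' parent recording, and breed-lineage labels with a low rate of cross-breed
#' mating. Defaults mirror a championship-scale studbook: 1,621 founders,
#' thirteen cohorts born 1999-2011 of 865 foals each (about 12,860 animals in
#' total) and a reference population of roughly 9% of cohort-born animals.
#'
#' @param n_founders number of founder animals (both parents unknown).
#' @param founder_sex_ratio proportion of founders that are male.
#' @param n_years number of birth-year cohorts to simulate.
#' @param birth_year_start calendar year of the first cohort.
#' @param offspring_per_year foals born per cohort.
#' @param n_active_sires sires licensed for breeding in any one year
#'   (the bottleneck knob).
#' @param sire_concentration concentration of the symmetric Dirichlet from
#'   which each year's sire-use weights are drawn; small values make a few
#'   sires dominate the crop, large values equalize use.
#' @param dam_reuse_rate probability that a dam that produced this year is
#'   available again next year (otherwise she rests a season).
#' @param missing_parent_rate probability that a recorded parent link is
#'   erased, independently for sire and dam (pedigree incompleteness knob).
#' @param n_breeds number of studbook (breed) labels; founders are assigned
#'   labels with geometrically decaying frequencies.
#' @param cross_breed_rate probability a mating ignores the dam's breed when
#'   choosing the sire.
#' @param reference_fraction probability that a cohort-born animal is flagged
#'   as part of the reference population.
#' @param min_parent_age,max_parent_age age window (years) in which an animal
#'   is an eligible parent.
#' @param seed integer seed; the same config and seed give a byte-identical
#'   pedigree.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_founders = 1621,
                       founder_sex_ratio = 0.3,
                       n_years = 13,
                       birth_year_start = 1999,
                       offspring_per_year = 865,
                       n_active_sires = 60,
                       sire_concentration = 0.3,
                       dam_reuse_rate = 0.5,
                       missing_parent_rate = 0.12,
                       n_breeds = 8,
                       cross_breed_rate = 0.1,
                       reference_fraction = 0.09,
                       min_parent_age = 3,
                       max_parent_age = 20,
                       seed = 1L) {
  cfg <- list(
    n_founders = as.integer(n_founders),
    founder_sex_ratio = founder_sex_ratio,
    n_years = as.integer(n_years),
    birth_year_start = as.integer(birth_year_start),
    offspring_per_year = as.integer(offspring_per_year),
    n_active_sires = as.integer(n_active_sires),
    sire_concentration = sire_concentration,
    dam_reuse_rate = dam_reuse_rate,
    missing_parent_rate = missing_parent_rate,
    n_breeds = as.integer(n_breeds),
    cross_breed_rate = cross_breed_rate,
    reference_fraction = reference_fraction,
    min_parent_age = as.integer(min_parent_age),
    max_parent_age = as.integer(max_parent_age),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(
      n_founders >= 1, n_years >= 1, offspring_per_year >= 1,
      n_active_sires >= 1, n_breeds >= 1, sire_concentration > 0,
      founder_sex_ratio >= 0, founder_sex_ratio <= 1,
      dam_reuse_rate >= 0, dam_reuse_rate <= 1,
      missing_parent_rate >= 0, missing_parent_rate <= 1,
      cross_breed_rate >= 0, cross_breed_rate <= 1,
      reference_fraction >= 0, reference_fraction <= 1,
      min_parent_age >= 1, max_parent_age > min_parent_age
    )
  })
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a studbook-like pedigree
#'
#' Founders receive birth years spread uniformly over the window that makes
#' them breeding-eligible in the first cohort year; cohort animals themselves
#' become eligible parents at `min_parent_age`, so generations overlap. Each
#' year `n_active_sires` males are licensed and their use weights are drawn
#' once from a symmetric Dirichlet(`sire_concentration`); each foal's sire is
#' drawn from that year's licensed pool (within the dam's breed, except for a
#' `cross_breed_rate` fraction of matings) and its dam uniformly from the
#' available mares. Breed labels are founder-lineage labels inherited from
#' the dam. After the crop is built, each recorded parent link is erased with
#' probability `missing_parent_rate`.
#'
#' @param config a [sim_config()].
#' @return A [pedigree()], topologically ordered, that passes
#'   [validate_pedigree()] with no errors.
#' @export
simulate_pedigree <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  y0 <- cfg$birth_year_start
  nf <- cfg$n_founders
  n_off <- cfg$n_years * cfg$offspring_per_year
  n <- nf + n_off

  id <- c(sprintf("F%05d", seq_len(nf)), sprintf("X%06d", seq_len(n_off)))
  sex <- character(n)
  n_male_f <- round(nf * cfg$founder_sex_ratio)
  sex[seq_len(nf)] <- sample(rep(c("M", "F"), c(n_male_f, nf - n_male_f)))
  # founders born so they are all eligible in the first cohort year
  birth_year <- integer(n)
  birth_year[seq_len(nf)] <- y0 - sample(cfg$min_parent_age:cfg$max_parent_age,
                                         nf, replace = TRUE)
  breed_labels <- sprintf("B%02d", seq_len(cfg$n_breeds))
  breed_p <- 0.5^(seq_len(cfg$n_breeds) - 1)
  breed <- character(n)
  breed[seq_len(nf)] <- sample(breed_labels, nf, replace = TRUE,
                               prob = breed_p / sum(breed_p))
  sire_i <- integer(n)   # row index of sire, 0 = unknown
  dam_i <- integer(n)

  if (sum(sex[seq_len(nf)] == "M") < cfg$n_active_sires) {
    stop("n_active_sires exceeds the number of male founders available in year 1")
  }

  dam_rested <- logical(n)  # produced last season and drew a rest year
  row <- nf
  for (yr in seq_len(cfg$n_years)) {
    year <- y0 + yr - 1L
    age <- year - birth_year[seq_len(row)]
    eligible <- age >= cfg$min_parent_age & age <= cfg$max_parent_age
    males <- which(eligible & sex[seq_len(row)] == "M")
    dams <- which(eligible & sex[seq_len(row)] == "F" & !dam_rested[seq_len(row)])
    if (!length(males) || !length(dams)) {
      stop("no eligible sires or dams in year ", year)
    }
    k <- min(cfg$n_active_sires, length(males))
    active <- sample(males, k)
    w <- stats::rgamma(k, shape = cfg$sire_concentration)
    if (sum(w) == 0) w <- rep(1, k)
    w <- w / sum(w)

    d_pick <- dams[sample.int(length(dams), cfg$offspring_per_year, replace = TRUE)]
    cross <- stats::runif(cfg$offspring_per_year) < cfg$cross_breed_rate
    s_pick <- integer(cfg$offspring_per_year)
    for (j in seq_len(cfg$offspring_per_year)) {
      pool <- active
      wj <- w
      if (!cross[j]) {
        same <- breed[active] == breed[d_pick[j]]
        if (any(same)) { pool <- active[same]; wj <- w[same] }
      }
      s_pick[j] <- if (length(pool) == 1L) pool else
        sample(pool, 1L, prob = wj / sum(wj))
    }

    idx <- row + seq_len(cfg$offspring_per_year)
    sire_i[idx] <- s_pick
    dam_i[idx] <- d_pick
    birth_year[idx] <- year
    sex[idx] <- sample(c("M", "F"), cfg$offspring_per_year, replace = TRUE)
    breed[idx] <- breed[d_pick]
    # dams that produced this season may rest next season
    dam_rested[seq_len(row)] <- FALSE
    produced <- unique(d_pick)
    dam_rested[produced] <- stats::runif(length(produced)) > cfg$dam_reuse_rate
    row <- row + cfg$offspring_per_year
  }

  sire <- ifelse(sire_i > 0L, id[pmax(sire_i, 1L)], NA_character_)
  dam <- ifelse(dam_i > 0L, id[pmax(dam_i, 1L)], NA_character_)
  if (cfg$missing_parent_rate > 0) {
    off <- (nf + 1L):n
    sire[off][stats::runif(n_off) < cfg$missing_parent_rate] <- NA_character_
    dam[off][stats::runif(n_off) < cfg$missing_parent_rate] <- NA_character_
  }

  in_ref <- c(rep(FALSE, nf),
              stats::runif(n_off) < cfg$reference_fraction)

  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   birth_year = birth_year, studbook = breed,
                   in_reference = in_ref, stringsAsFactors = FALSE)
  # parents whose every offspring link was erased stay only if still referenced
  referenced <- unique(c(sire[!is.na(sire)], dam[!is.na(dam)]))
  drop <- is.na(df$sire) & is.na(df$dam) & !(df$id %in% referenced) &
    !df$in_reference & seq_len(n) <= nf & cfg$missing_parent_rate > 0 &
    !(df$id %in% c(sire, dam))
  # founders that never bred at all are kept; only erasure-orphaned ones go
  bred <- df$id %in% c(ifelse(sire_i > 0L, id[pmax(sire_i, 1L)], NA),
                       ifelse(dam_i > 0L, id[pmax(dam_i, 1L)], NA))
  df <- df[!(drop & bred), , drop = FALSE]
  pedigree(df)
}

#' Canonical toy pedigrees for closed-form checks
#'
#' Small fixed pedigrees whose inbreeding, kinship and founder statistics
#' have textbook closed forms:
#' \describe{
#'   \item{full_sib_mating}{founders A, B; full sibs C, D; E = C x D with
#'     `in_reference = TRUE`. F(E) = 0.25.}
#'   \item{half_sib_mating}{common sire S, founder dams D1, D2; half sibs
#'     H1, H2; offspring O = H1 x H2 in reference. F(O) = 0.125.}
#'   \item{parent_offspring}{founders A, B; C = A x B; O = A x C in
#'     reference. F(O) = 0.25.}
#'   \item{founders_only}{`n` unrelated founders, all in reference.}
#'   \item{chain15}{a single lineage with a longest ancestral path of
#'     exactly 15 generations.}
#'   \item{two_breed}{two closed four-animal breed lineages with one inbred
#'     offspring each; no cross-breed relationship.}
#' }
#'
#' @param name toy name.
#' @param n number of founders for `founders_only`.
#' @return A [pedigree()].
#' @export
make_toy <- function(name = c("full_sib_mating", "half_sib_mating",
                              "parent_offspring", "founders_only",
                              "chain15", "two_breed"),
                     n = 5L) {
  name <- match.arg(name)
  df <- switch(
    name,
    full_sib_mating = data.frame(
      id = c("A", "B", "C", "D", "E"),
      sire = c(NA, NA, "A", "A", "C"),
      dam = c(NA, NA, "B", "B", "D"),
      sex = c("M", "F", "M", "F", "U"),
      birth_year = c(2000L, 2000L, 2004L, 2004L, 2008L),
      in_reference = c(FALSE, FALSE, FALSE, FALSE, TRUE)
    ),
    half_sib_mating = data.frame(
      id = c("S", "D1", "D2", "H1", "H2", "O"),
      sire = c(NA, NA, NA, "S", "S", "H1"),
      dam = c(NA, NA, NA, "D1", "D2", "H2"),
      sex = c("M", "F", "F", "M", "F", "U"),
      birth_year = c(2000L, 2000L, 2000L, 2004L, 2004L, 2008L),
      in_reference = c(rep(FALSE, 5), TRUE)
    ),
    parent_offspring = data.frame(
      id = c("A", "B", "C", "O"),
      sire = c(NA, NA, "A", "A"),
      dam = c(NA, NA, "B", "C"),
      sex = c("M", "F", "F", "U"),
      birth_year = c(2000L, 2000L, 2004L, 2008L),
      in_reference = c(FALSE, FALSE, FALSE, TRUE)
    ),
    founders_only = data.frame(
      id = sprintf("P%02d", seq_len(n)),
      sire = NA_character_, dam = NA_character_,
      sex = rep_len(c("M", "F"), n),
      birth_year = 2000L, in_reference = TRUE
    ),
    chain15 = {
      ids <- sprintf("G%02d", 0:15)
      mates <- sprintf("M%02d", 1:15)
      data.frame(
        id = c(ids[1], rbind(mates, ids[-1])),
        sire = c(NA, rbind(NA_character_, ids[-length(ids)])),
        dam = c(NA, rbind(NA_character_, mates)),
        sex = c("M", rep(c("F", "M"), 15)),
        birth_year = c(1950L, rbind(1950L + 4L * (0:14), 1954L + 4L * (0:14))),
        in_reference = c(rep(FALSE, 30), TRUE)
      )
    },
    two_breed = data.frame(
      id = c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4"),
      sire = c(NA, NA, "A1", "A1", NA, NA, "B1", "B1"),
      dam = c(NA, NA, "A2", "A2", NA, NA, "B2", "B2"),
      sex = c("M", "F", "M", "F", "M", "F", "M", "F"),
      birth_year = rep(c(2000L, 2000L, 2004L, 2004L), 2),
      studbook = rep(c("alpha", "beta"), each = 4),
      in_reference = rep(c(FALSE, FALSE, TRUE, TRUE), 2)
    )
  )
  pedigree(df)
}
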